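# Preprocessing: front-end band-pass, section extraction, band
# decomposition, and sliding-window fragmentation.

#' Canonical seven-band definition
#'
#' delta 1-3, theta 4-7, low alpha 8-10, high alpha 10-12, low beta 12-20,
#' high beta 20-30 and gamma 31-50 Hz. Because the front-end band-pass cuts
#' at 45 Hz, the gamma band-pass filter is realized as 31-45 Hz (see
#' [decomposeBands()]).
#'
#' @return `data.frame` with columns `name`, `f_lo`, `f_hi`.
#' @export
canonicalBands <- function() {
  data.frame(name = c("delta", "theta", "alpha_l", "alpha_h",
                      "beta_l", "beta_h", "gamma"),
             f_lo = c(1, 4, 8, 10, 12, 20, 31),
             f_hi = c(3, 7, 10, 12, 20, 30, 50),
             stringsAsFactors = FALSE)
}

# Butterworth designs are pure functions of (order, band, fs): cache them.
.filterCache <- new.env(parent = emptyenv())

.butterCached <- function(order, fLo, fHi, fs) {
  key <- paste(order, fLo, fHi, fs, sep = "|")
  filt <- .filterCache[[key]]
  if (is.null(filt)) {
    arma <- signal::butter(order, c(fLo, fHi) / (fs / 2), type = "pass")
    n <- max(length(arma$a), length(arma$b))
    b <- c(arma$b, rep(0, n - length(arma$b)))
    a <- c(arma$a, rep(0, n - length(arma$a))) / arma$a[1]
    # steady-state filter state per unit input (step-response matching),
    # used to suppress start-up transients in each zero-phase pass
    comp <- rbind(-a[-1], cbind(diag(n - 2), 0))
    zi <- solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
    filt <- list(b = b, a = a, zi = zi)
    .filterCache[[key]] <- filt
  }
  filt
}

# Autoregressive signal extension: continues x beyond its last sample with
# the recursion of an AR model fitted to the tail, so the padded boundary
# has no kink to ring on (tones continue perfectly, noise continues
# statistically).
.arExtend <- function(x, pad, ord = 16) {
  n <- length(x)
  fitN <- min(n, max(4L * pad, 8L * ord))
  tl <- x[(n - fitN + 1):n]
  fit <- tryCatch(stats::ar.yw(tl, aic = FALSE,
                               order.max = min(ord, fitN - 2L)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0L || !is.finite(fit$var.pred))
    return(rep(x[n], pad))
  p <- length(fit$ar)
  buf <- c(tl[(fitN - p + 1):fitN] - fit$x.mean, numeric(pad))
  for (k in seq_len(pad))
    buf[p + k] <- sum(fit$ar * buf[(p + k - 1):k])
  buf[(p + 1):(p + pad)] + fit$x.mean
}

# AR-extend each column on both ends.
.arPadMatrix <- function(x, pad) {
  out <- matrix(0, nrow(x) + 2L * pad, ncol(x))
  for (j in seq_len(ncol(x))) {
    out[, j] <- c(rev(.arExtend(rev(x[, j]), pad)), x[, j],
                  .arExtend(x[, j], pad))
  }
  out
}

# Zero-phase (forward-backward) Butterworth application on each column.
# arPad = TRUE pads by AR extension (clean edges for stand-alone use);
# arPad = FALSE uses cheap odd-reflection padding, appropriate when the
# caller trims a real-data margin anyway.
.filtfiltMatrix <- function(filt, x, arPad = FALSE, fs = NULL) {
  x <- .asSampleMatrix(x)
  if (arPad) {
    pad <- min(nrow(x) - 1L, as.integer(2 * round(fs)))
    xp <- .arPadMatrix(x, pad)
    y <- .iirFiltfiltMat(filt$b, filt$a, filt$zi, xp, 0L)
    y[(pad + 1):(pad + nrow(x)), , drop = FALSE]
  } else {
    pad <- max(3L * length(filt$a), 48L)
    .iirFiltfiltMat(filt$b, filt$a, filt$zi, x, as.integer(pad))
  }
}

#' Zero-phase Butterworth band-pass front-end
#'
#' Filters each channel forward and backward (zero phase, so section
#' alignment is preserved) with an order-`order` Butterworth band-pass.
#' The default 1-45 Hz pass band removes baseline drift and mains
#' interference.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs Sampling rate (Hz).
#' @param fLo,fHi Pass-band edges (Hz); `fHi` must be below Nyquist.
#' @param order Butterworth order per pass (default 6).
#' @param arPad Pad by autoregressive signal extension before filtering
#'   (clean edges; default). Internal callers that trim a real-data margin
#'   disable it.
#' @return Filtered object of the same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 256)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
#' y <- bandpassFilter(x, 256)   # keeps 10 Hz, rejects 60 Hz
#' @export
bandpassFilter <- function(x, fs, fLo = 1, fHi = 45, order = 6,
                           arPad = TRUE) {
  if (!(fLo > 0 && fLo < fHi)) stop("invalid band: need 0 < fLo < fHi", call. = FALSE)
  if (fHi >= fs / 2) stop("invalid band: fHi must be < fs/2", call. = FALSE)
  vec <- is.null(dim(x))
  m <- .asSampleMatrix(x)
  if (nrow(m) <= 3 * 2 * order)
    stop("signal too short for the requested filter order", call. = FALSE)
  out <- .filtfiltMatrix(.butterCached(order, fLo, fHi, fs), m,
                         arPad = arPad, fs = fs)
  if (vec) drop(out) else out
}

#' Cut the four analysis sections from a session
#'
#' `pre` is the last `sectionLengthS` seconds before viewing onset, `begin`
#' the first `sectionLengthS` seconds of viewing, `end` the last
#' `sectionLengthS` seconds of viewing, and `post` the first
#' `sectionLengthS` seconds after viewing offset. If the viewing is shorter
#' than twice the section length, `begin` and `end` overlap and a warning is
#' recorded.
#'
#' @param recording An [EegRecording-class] (or a list with `samples`,
#'   `fs`, `watchStart`, `watchEnd`).
#' @param sectionLengthS Section length in seconds (default 30).
#' @return A [SectionSet-class].
#' @export
extractSections <- function(recording, sectionLengthS = 30) {
  if (is(recording, "EegRecording")) {
    x <- recording@samples; fs <- recording@fs
    ws <- recording@watchStart; we <- recording@watchEnd
    pid <- recording@participantId; sid <- recording@segmentId
  } else {
    x <- .asSampleMatrix(recording$samples); fs <- recording$fs
    ws <- recording$watchStart; we <- recording$watchEnd
    pid <- recording$participantId %||% ""; sid <- recording$segmentId %||% ""
  }
  if (is.null(ws) || is.null(we) || is.na(ws) || is.na(we))
    stop("marker error: watchStart/watchEnd missing", call. = FALSE)
  L <- round(sectionLengthS * fs)
  n <- nrow(x)
  if (ws < L || n - we < L)
    stop("insufficient data: rest shorter than the section length", call. = FALSE)
  watchS <- (we - ws) / fs
  overlap <- max(0, 2 * sectionLengthS - watchS)
  if (overlap > 0)
    warning(sprintf("begin and end sections overlap by %g s (viewing %g s < 2 x %g s)",
                    overlap, watchS, sectionLengthS), call. = FALSE)
  # markers are 0-based half-open; R rows are 1-based
  sec <- function(from) x[(from + 1):(from + L), , drop = FALSE]
  new("SectionSet",
      pre = sec(ws - L), begin = sec(ws), end = sec(we - L), post = sec(we),
      fs = fs, sectionLengthS = sectionLengthS, overlapS = overlap,
      participantId = pid, segmentId = sid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose a signal into the seven canonical bands
#'
#' Applies one order-4 zero-phase Butterworth band-pass per band. Upper band
#' edges are capped at `fHiCap` (45 Hz by default) to honor the front-end
#' pass band, so the 31-50 Hz gamma definition is filtered as 31-45 Hz.
#' Shared edges (e.g. 12 Hz) belong to both adjacent filters, so band
#' energies are approximately, not exactly, additive.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs Sampling rate (Hz).
#' @param bands Band definition `data.frame` (`name`, `f_lo`, `f_hi`).
#' @param order Per-band Butterworth order (default 4).
#' @param fHiCap Upper cap applied to every band's `f_hi` (Hz).
#' @param arPad Pad by autoregressive signal extension (shared across the
#'   filterbank) before filtering; default `TRUE`.
#' @return Named list of filtered objects, one per band, same shape as `x`.
#' @export
decomposeBands <- function(x, fs, bands = canonicalBands(), order = 4,
                           fHiCap = 45, arPad = TRUE) {
  if (is.null(bands) || nrow(bands) == 0L)
    stop("configuration error: empty band list", call. = FALSE)
  vec <- is.null(dim(x))
  m <- .asSampleMatrix(x)
  n <- nrow(m)
  pad <- 0L
  if (arPad) {
    pad <- min(n - 1L, as.integer(2 * round(fs)))
    m <- .arPadMatrix(m, pad)
  }
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    hi <- min(bands$f_hi[b], fHiCap)
    if (hi >= fs / 2) stop("band above Nyquist: ", bands$name[b], call. = FALSE)
    filt <- .butterCached(order, bands$f_lo[b], hi, fs)
    y <- if (pad > 0) {
      .iirFiltfiltMat(filt$b, filt$a, filt$zi, m, 0L)[(pad + 1):(pad + n), ,
                                                      drop = FALSE]
    } else {
      .filtfiltMatrix(filt, m)
    }
    out[[b]] <- if (vec) drop(y) else y
  }
  out
}

#' Sliding-window fragment count
#'
#' The data-enhancement count `N = (L - W) / step + 1` (floored), for a
#' segment of `L` seconds cut into `W`-second windows advanced by `step`
#' seconds.
#'
#' @param lengthS,windowS,stepS Segment length, window size and step (s).
#' @return Integer fragment count (0 if the window exceeds the segment).
#' @examples
#' fragmentCount(30, 2, 1)   # 29
#' fragmentCount(60, 8, 4)   # 14
#' @export
fragmentCount <- function(lengthS, windowS, stepS) {
  if (stepS <= 0) stop("stepS must be > 0", call. = FALSE)
  if (windowS > lengthS) return(0L)
  as.integer(floor((lengthS - windowS) / stepS) + 1)
}

#' Cut a signal into overlapping fragments
#'
#' Slides a `windowS`-second window in `stepS`-second steps; all fragments
#' inherit their source segment's label downstream. A window longer than the
#' signal yields an empty list with a warning.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs Sampling rate (Hz).
#' @param windowS,stepS Window and step in seconds.
#' @return List of fragments; each has `samples`, 1-based `index`, and
#'   `tStartS` (offset of the window start within the signal, seconds).
#' @export
fragmentSignal <- function(x, fs, windowS, stepS) {
  m <- .asSampleMatrix(x)
  lengthS <- nrow(m) / fs
  nFrag <- fragmentCount(lengthS, windowS, stepS)
  if (nFrag == 0L) {
    warning("window longer than signal: returning no fragments", call. = FALSE)
    return(list())
  }
  W <- round(windowS * fs); S <- round(stepS * fs)
  lapply(seq_len(nFrag), function(i) {
    from <- (i - 1L) * S
    list(samples = m[(from + 1):(from + W), , drop = FALSE],
         index = i, tStartS = from / fs)
  })
}
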