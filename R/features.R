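# Spectral feature bank: energy, energy ratio, energy entropy, differential
# entropy, AR power spectral density, and hemispheric asymmetries.

#' Signal energy
#'
#' `E = sum(x^2)` (uV^2 * samples); by Parseval's theorem this equals
#' `sum(abs(fft(x))^2) / n`.
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @examples
#' bandEnergy(sin(2 * pi * 10 * seq(0, 1 - 1/256, by = 1/256)))  # n/2 = 128
#' @export
bandEnergy <- function(x) {
  if (length(x) == 0L) stop("length error: empty vector", call. = FALSE)
  sum(x^2)
}

#' Energy ratio between two bands
#'
#' @param eA,eB Band energies; `eB` must be positive.
#' @return `eA / eB`.
#' @export
energyRatio <- function(eA, eB) {
  if (any(eB <= 0)) stop("division guard: denominator energy must be > 0",
                         call. = FALSE)
  eA / eB
}

#' Energy entropy of a band-limited signal
#'
#' The signal is cut into `subwindowS`-second sub-windows and the energy
#' fractions `p_i = E_i / sum(E)` are formed. The default `"shannon"` mode
#' returns `-sum(p_i * log(p_i))` (nats, in `[0, log m]`); the `"literal"`
#' mode returns `sum(log(p_i^2))`, the form some of the feature literature
#' prints.
#'
#' @param x Numeric vector spanning at least two sub-windows.
#' @param fs Sampling rate (Hz).
#' @param subwindowS Sub-window length in seconds (default 1).
#' @param mode `"shannon"` (default) or `"literal"`.
#' @return Scalar entropy in nats.
#' @export
energyEntropy <- function(x, fs, subwindowS = 1, mode = c("shannon", "literal")) {
  mode <- match.arg(mode)
  L <- round(subwindowS * fs)
  m <- floor(length(x) / L)
  if (m < 2L) stop("need at least two sub-windows", call. = FALSE)
  e <- colSums(matrix(x[seq_len(m * L)], nrow = L)^2)
  tot <- sum(e)
  if (tot <= 0) stop("degenerate input: zero total energy", call. = FALSE)
  p <- e / tot
  if (mode == "shannon") {
    nz <- p > 0
    -sum(p[nz] * log(p[nz]))
  } else {
    2 * sum(log(p))
  }
}

#' Differential entropy of a band-limited signal
#'
#' Under the Gaussian assumption standard for band-limited EEG,
#' `DE = 1/2 * log(2 * pi * e * sigma^2)` nats, with `sigma^2` the unbiased
#' sample variance.
#'
#' @param x Numeric vector with positive sample variance.
#' @return Scalar in nats; `~1.4189` for a unit-variance signal.
#' @export
differentialEntropy <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0)
    stop("degenerate input: zero variance", call. = FALSE)
  0.5 * log(2 * pi * exp(1) * v)
}

# AR spectrum (two-sided density, power/Hz) evaluated on frequencies f for
# AR coefficients a (x_t = sum a_k x_{t-k} + e) and innovation variance v.
.arSpectrum <- function(a, v, fs, f) {
  ek <- exp(-2i * pi * outer(seq_along(a), f) / fs)
  (v / fs) / abs(1 - as.vector(a %*% ek))^2
}

#' Band-mean autoregressive power spectral density
#'
#' Fits a Yule-Walker autoregressive model of order `arOrder` (via
#' [stats::ar.yw]) and returns the mean of the AR power spectrum
#' `sigma^2 / (fs * |1 - sum(a_k exp(-2i pi f k / fs))|^2)` over the grid
#' points of a `nFreq`-point `[0, fs/2]` grid falling inside
#' `[fLo, fHi]`. For unit-variance white noise this is flat at `1/fs`.
#' If the AR fit fails, the periodogram mean over the band is returned with
#' a warning.
#'
#' @param x Numeric vector, longer than `3 * arOrder`, non-degenerate.
#' @param fs Sampling rate (Hz).
#' @param fLo,fHi Band over which the spectrum is averaged (Hz).
#' @param arOrder AR model order (default 8).
#' @param nFreq Number of grid points spanning `[0, fs/2]` (default 512).
#' @return Scalar band-mean PSD (power/Hz).
#' @export
bandPsd <- function(x, fs, fLo, fHi, arOrder = 8, nFreq = 512) {
  if (length(x) <= 3 * arOrder)
    stop("signal too short for AR order", call. = FALSE)
  if (stats::var(x) == 0)
    stop("estimation error: zero-variance input", call. = FALSE)
  grid <- seq(0, fs / 2, length.out = nFreq)
  f <- grid[grid >= fLo & grid <= fHi]
  if (!length(f)) stop("band contains no grid frequencies", call. = FALSE)
  fit <- tryCatch(stats::ar.yw(x, aic = FALSE, order.max = arOrder),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$var.pred) || fit$var.pred <= 0) {
    warning("AR fit ill-conditioned; falling back to periodogram band mean",
            call. = FALSE)
    n <- length(x)
    pg <- abs(stats::fft(x - mean(x)))^2 / (n * fs)  # two-sided density
    fr <- (seq_len(n) - 1) * fs / n
    sel <- fr >= fLo & fr <= fHi
    return(mean(pg[sel]))
  }
  mean(.arSpectrum(fit$ar, fit$var.pred, fs, f))
}

#' Hemispheric asymmetry features
#'
#' Given per-band features for the left (FP1) and right (FP2) channels,
#' returns the four asymmetry families with the field's sign conventions:
#' `ASM = E(right) - E(left)`, `ERASM = ER(right) - ER(left)`,
#' `DASM = DE(left) - DE(right)`, `RASM = DE(left) / DE(right)`.
#'
#' @param left,right Lists with named numeric components `E` (energy per
#'   band), `DE` (differential entropy per band) and `ER` (energy ratio per
#'   band pair); any component may be omitted.
#' @return Named numeric vector (`ASM__band`, `ERASM__b1__b2`,
#'   `DASM__band`, `RASM__band`).
#' @export
asymmetryFeatures <- function(left, right) {
  out <- numeric(0)
  if (!is.null(left$E)) {
    nm <- intersect(names(left$E), names(right$E))
    out <- c(out, stats::setNames(right$E[nm] - left$E[nm], paste0("ASM__", nm)))
  }
  if (!is.null(left$ER)) {
    nm <- intersect(names(left$ER), names(right$ER))
    out <- c(out, stats::setNames(right$ER[nm] - left$ER[nm], paste0("ERASM__", nm)))
  }
  if (!is.null(left$DE)) {
    nm <- intersect(names(left$DE), names(right$DE))
    out <- c(out, stats::setNames(left$DE[nm] - right$DE[nm], paste0("DASM__", nm)))
    if (any(right$DE[nm] == 0))
      stop("division guard: DE(right) = 0 in RASM", call. = FALSE)
    out <- c(out, stats::setNames(left$DE[nm] / right$DE[nm], paste0("RASM__", nm)))
  }
  out
}

#' Enumerate the feature dictionary
#'
#' The `"model"` set is the 147-column regression dictionary:
#' families E, EE, DE, PSD over 7 bands x 3 channels (84 columns) plus ER
#' over the 21 ordered band pairs x 3 channels (63 columns). The `"stats"`
#' set appends the asymmetry families used by the group statistics with
#' their alpha restriction: ASM, DASM, RASM over `alpha_l`/`alpha_h` and
#' ERASM over all 21 band pairs (174 columns total). `"all"` lifts the
#' alpha restriction (ASM/DASM/RASM over all 7 bands; 189 columns).
#' Column order is a pure function of the inputs. Names follow
#' `family__band[__band2][__channel]`.
#'
#' @param bands Character vector of band names in canonical order.
#' @param channels Character vector of channel names (FP1, FPZ, FP2).
#' @param set `"model"`, `"stats"` or `"all"`.
#' @return `data.frame` with columns `name`, `family`, `band`, `band2`,
#'   `channel` (`NA` where not applicable).
#' @examples
#' nrow(featureKeySet())                  # 147
#' nrow(featureKeySet(set = "stats"))     # 174
#' @export
featureKeySet <- function(bands = canonicalBands()$name,
                          channels = c("FP1", "FPZ", "FP2"),
                          set = c("model", "stats", "all")) {
  set <- match.arg(set)
  rows <- list()
  add <- function(family, band, band2 = NA_character_, channel = NA_character_) {
    name <- paste(c(family, band, if (!is.na(band2)) band2,
                    if (!is.na(channel)) channel), collapse = "__")
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family, band = band, band2 = band2,
      channel = channel, stringsAsFactors = FALSE)
  }
  for (fam in c("E", "EE", "DE", "PSD"))
    for (b in bands) for (ch in channels) add(fam, b, channel = ch)
  nb <- length(bands)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb)
    for (ch in channels) add("ER", bands[i], bands[j], ch)
  if (set != "model") {
    alpha <- if (set == "stats") intersect(c("alpha_l", "alpha_h"), bands) else bands
    for (b in alpha) add("ASM", b)
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) add("ERASM", bands[i], bands[j])
    for (b in alpha) add("DASM", b)
    for (b in alpha) add("RASM", b)
  }
  do.call(rbind, rows)
}

# ---- vectorized per-epoch engine -------------------------------------------

# Batch Levinson-Durbin: R is epochs x (p+1) autocovariances (lag 0..p).
# Returns AR coefficients (epochs x p) and innovation variance, replicating
# stats::ar.yw including its n/(n - p - 1) variance inflation.
.levinsonBatch <- function(R, p, n) {
  m <- nrow(R)
  a <- matrix(0, m, p)
  e <- R[, 1]
  for (k in seq_len(p)) {
    acc <- if (k == 1) R[, 2] else
      R[, k + 1] - rowSums(a[, 1:(k - 1), drop = FALSE] * R[, k:2, drop = FALSE])
    kk <- acc / e
    kk[!is.finite(kk)] <- 0
    if (k > 1)
      a[, 1:(k - 1)] <- a[, 1:(k - 1), drop = FALSE] -
        kk * a[, (k - 1):1, drop = FALSE]
    a[, k] <- kk
    e <- e * (1 - kk^2)
  }
  list(ar = a, varPred = e * n / (n - p - 1))
}

# Per-epoch features for one band: m is an spe x K matrix whose columns are
# epochs (channels may be stacked side by side). Returns per-column vectors:
# E, DE, EE, PSD (band mean).
.epochFeaturesMatrix <- function(m, fs, spe, fLo, fHi,
                                 eeSubwindowS = 0.125, arOrder = 8,
                                 nFreq = 512) {
  nEpochs <- ncol(m)
  E <- colSums(m^2)
  mu <- colMeans(m)
  v <- (E - spe * mu^2) / (spe - 1)         # unbiased per-epoch variance
  v[v < 0] <- 0
  DE <- ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), NA_real_)
  # energy entropy over eeSubwindowS sub-windows inside each epoch
  swLen <- max(1L, round(eeSubwindowS * fs))
  nsw <- floor(spe / swLen)
  sub <- colSums(matrix(m[seq_len(nsw * swLen), ], nrow = swLen)^2)
  sub <- matrix(sub, nrow = nsw)
  tot <- colSums(sub)
  p <- sweep(sub, 2, tot, "/")
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  EE <- -colSums(plogp)
  EE[tot <= 0] <- NA_real_
  # Yule-Walker AR spectrum, band mean
  md <- sweep(m, 2, mu)
  R <- vapply(0:arOrder, function(k) {
    if (k == 0) colSums(md^2) / spe
    else colSums(md[1:(spe - k), , drop = FALSE] *
                 md[(k + 1):spe, , drop = FALSE]) / spe
  }, numeric(nEpochs))
  if (nEpochs == 1L) R <- matrix(R, nrow = 1L)
  lv <- .levinsonBatch(R, arOrder, spe)
  grid <- seq(0, fs / 2, length.out = nFreq)
  f <- grid[grid >= fLo & grid <= fHi]
  ek <- exp(-2i * pi * outer(seq_len(arOrder), f) / fs)
  denom <- abs(1 - lv$ar %*% ek)^2
  PSD <- rowMeans(sweep(1 / denom, 1, lv$varPred / fs, "*"))
  PSD[v <= 0] <- NA_real_
  list(E = E, DE = DE, EE = EE, PSD = PSD)
}

# Full per-epoch feature block for a multichannel section already cut to a
# whole number of epochs. Returns an epochs x nrow(keys) matrix.
.epochFeatureBlock <- function(x, fs, keys, bands = canonicalBands(),
                               channels = c("FP1", "FPZ", "FP2"),
                               epochS = 1, eeSubwindowS = 0.125,
                               arOrder = 8, bandSignals = NULL) {
  x <- .asSampleMatrix(x)
  spe <- round(epochS * fs)
  nEpochs <- floor(nrow(x) / spe)
  if (nEpochs < 1L) stop("section shorter than one epoch", call. = FALSE)
  if (is.null(bandSignals)) bandSignals <- decomposeBands(x, fs, bands)
  nb <- nrow(bands); nc <- length(channels)
  fam <- c("E", "DE", "EE", "PSD")
  store <- array(NA_real_, c(nEpochs, nb, nc, length(fam)),
                 dimnames = list(NULL, bands$name, channels, fam))
  for (b in seq_len(nb)) {
    # stack the channels' epochs as columns of one spe x (nEpochs*nc) matrix
    m <- matrix(bandSignals[[b]][seq_len(spe * nEpochs), , drop = FALSE],
                nrow = spe)
    r <- .epochFeaturesMatrix(m, fs, spe, bands$f_lo[b],
                              min(bands$f_hi[b], 45), eeSubwindowS, arOrder)
    for (ch in seq_len(nc)) {
      cols <- (ch - 1L) * nEpochs + seq_len(nEpochs)
      store[, b, ch, "E"] <- r$E[cols]
      store[, b, ch, "DE"] <- r$DE[cols]
      store[, b, ch, "EE"] <- r$EE[cols]
      store[, b, ch, "PSD"] <- r$PSD[cols]
    }
  }
  iBand <- match(keys$band, bands$name)
  iBand2 <- match(keys$band2, bands$name)
  iChan <- match(keys$channel, channels)
  iL <- match("FP1", channels); iR <- match("FP2", channels)
  out <- matrix(NA_real_, nEpochs, nrow(keys),
                dimnames = list(NULL, keys$name))
  for (i in seq_len(nrow(keys))) {
    out[, i] <- switch(keys$family[i],
      E = store[, iBand[i], iChan[i], 1L],
      DE = store[, iBand[i], iChan[i], 2L],
      EE = store[, iBand[i], iChan[i], 3L],
      PSD = store[, iBand[i], iChan[i], 4L],
      ER = store[, iBand[i], iChan[i], 1L] / store[, iBand2[i], iChan[i], 1L],
      ASM = store[, iBand[i], iR, 1L] - store[, iBand[i], iL, 1L],
      ERASM = store[, iBand[i], iR, 1L] / store[, iBand2[i], iR, 1L] -
              store[, iBand[i], iL, 1L] / store[, iBand2[i], iL, 1L],
      DASM = store[, iBand[i], iL, 2L] - store[, iBand[i], iR, 2L],
      RASM = store[, iBand[i], iL, 2L] / store[, iBand[i], iR, 2L],
      stop("unknown feature family: ", keys$family[i]))
  }
  out
}
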