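# Synthetic cohort generator: labeled frontal-EEG viewing sessions whose
# band-power structure follows a latent relaxation trajectory.

# Reference log band powers (natural log of uV^2) at the reference R-state
# (r = 5): a 1/f-like profile with an alpha bump, giving a broadband RMS of
# roughly 10-15 uV, typical for eyes-open prefrontal EEG.
.BASE_LOG_POWER <- c(delta = 4.2, theta = 3.3, alpha_l = 3.1, alpha_h = 2.9,
                     beta_l = 2.3, beta_h = 1.8, gamma = 1.2)
.R_REFERENCE <- 5       # R-state at which band powers sit at their base level
.R_BASELINE <- 3        # latent relaxation during the pre-viewing rest

# Between/within-participant variability of log band power (chosen once as
# plausible for a homogeneous young-adult cohort; see the methods vignette):
.SD_PARTICIPANT_GAIN <- 0.3   # broadband gain, shared across bands
.SD_PARTICIPANT_BAND <- 0.1   # per-band offset
.SD_SEGMENT_BAND <- 0.05      # per-segment per-band jitter

#' The paper-style scene catalogue used by default
#'
#' Four sightseeing scenes with durations between 90 and 199 seconds.
#' @return `data.frame` with columns `name`, `duration_s`.
#' @export
defaultScenes <- function() {
  data.frame(name = c("NationalPark", "SnowMountain", "GreatWall", "Yunnan"),
             duration_s = c(199, 156, 90, 144),
             stringsAsFactors = FALSE)
}

#' Create a synthetic-experiment configuration
#'
#' Defaults reproduce the study conditions the package targets: 26
#' participants each viewing three of four scenes (90-199 s) at 256 Hz with
#' 2-minute rests, and a dropout fraction that flags 7 of the 78 segments
#' unusable (leaving 71). Band-response slopes default to a mild
#' relaxation signature (alpha up, beta down); set all slopes to 0 for a
#' null cohort.
#'
#' @param nParticipants Cohort size.
#' @param scenes Scene catalogue; see [defaultScenes()].
#' @param fs Sampling rate (Hz).
#' @param channels Channel montage; must be FP1, FPZ, FP2.
#' @param restDurationS Rest duration before/after each viewing (s).
#' @param bandResponse Named numeric, slope of log band power per unit
#'   R-state (bands not named get slope 0).
#' @param asymmetryResponse Slope of (FP2 - FP1) alpha log power per unit
#'   R-state.
#' @param noiseFloor Pink-noise power relative to total reference band power.
#' @param labelNoiseSd SD of the reported label around the latent R-state.
#' @param segmentDropout Fraction of segments flagged unusable
#'   (`round(fraction * n)` segments, chosen at random).
#' @param seed Integer master seed.
#' @return A [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nParticipants = 4, seed = 1)
#' cfg
#' @export
synthConfig <- function(nParticipants = 26L,
                        scenes = defaultScenes(),
                        fs = 256,
                        channels = c("FP1", "FPZ", "FP2"),
                        restDurationS = 120,
                        bandResponse = c(alpha_l = 0.2, alpha_h = 0.2,
                                         beta_l = -0.1, beta_h = -0.2),
                        asymmetryResponse = 0.1,
                        noiseFloor = 0.5,
                        labelNoiseSd = 0.5,
                        segmentDropout = 7 / 78,
                        seed = 1L) {
  resp <- stats::setNames(rep(0, length(.BASE_LOG_POWER)), names(.BASE_LOG_POWER))
  if (length(bandResponse)) {
    bad <- setdiff(names(bandResponse), names(resp))
    if (length(bad)) stop("unknown band(s) in bandResponse: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    resp[names(bandResponse)] <- bandResponse
  }
  new("SynthConfig", nParticipants = as.integer(nParticipants),
      scenes = scenes, fs = fs, channels = toupper(channels),
      restDurationS = restDurationS, bandResponse = resp,
      asymmetryResponse = asymmetryResponse, noiseFloor = noiseFloor,
      labelNoiseSd = labelNoiseSd, segmentDropout = segmentDropout,
      seed = as.integer(seed))
}

#' Band-limited Gaussian noise
#'
#' Synthesizes a zero-mean Gaussian signal whose spectral support lies in
#' `[fLo, fHi]`: independent complex-Gaussian Fourier coefficients are drawn
#' on the in-band frequency bins and inverted, then the vector is rescaled
#' to the requested variance exactly.
#'
#' @param fLo,fHi Band edges in Hz; `0 < fLo < fHi <= fs/2`.
#' @param durationS Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param power Target variance; `0` returns an all-zero vector.
#' @param seed Optional seed; `NULL` uses (and advances) the current RNG.
#' @return Numeric vector of length `round(durationS * fs)`.
#' @examples
#' x <- bandLimitedNoise(8, 10, 2, 256, power = 1, seed = 1)
#' var(x)
#' @export
bandLimitedNoise <- function(fLo, fHi, durationS, fs, power = 1, seed = NULL) {
  if (!(fLo > 0 && fLo < fHi && fHi <= fs / 2))
    stop("invalid band: need 0 < fLo < fHi <= fs/2", call. = FALSE)
  if (durationS <= 0) stop("durationS must be > 0", call. = FALSE)
  if (power < 0) stop("power must be >= 0", call. = FALSE)
  run <- function() {
    n <- round(durationS * fs)
    x <- .spectralNoise(n, fs, function(f) as.numeric(f >= fLo & f <= fHi))
    if (power == 0) return(numeric(n))
    s <- stats::sd(x)
    if (s == 0) stop("band contains no Fourier frequencies at this duration",
                     call. = FALSE)
    x * sqrt(power) / s
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

# Gaussian noise with per-bin spectral power weight(f); unscaled output.
# Synthesis runs at the next 2-3-5-smooth length (fast FFT) and the first n
# samples are returned; the process is stationary, so truncation only trims
# the realization.
.spectralNoise <- function(n, fs, weight) {
  nf <- stats::nextn(n, c(2, 3, 5))
  kMax <- floor((nf - 1) / 2)
  if (kMax < 1L) return(numeric(n))
  f <- (1:kMax) * fs / nf
  w <- weight(f) * nf / n      # weights are calibrated for length n
  X <- complex(real = numeric(nf), imaginary = numeric(nf))
  sel <- which(w > 0)
  if (length(sel)) {
    z <- complex(real = stats::rnorm(length(sel)),
                 imaginary = stats::rnorm(length(sel))) * sqrt(w[sel] / 2)
    X[sel + 1L] <- z
    X[nf - sel + 1L] <- Conj(z)
  }
  (Re(stats::fft(X, inverse = TRUE)) / sqrt(nf))[seq_len(n)]
}

# Two independent realizations from one inverse FFT: without the Hermitian
# constraint the transform of a circular complex Gaussian spectrum has
# independent real and imaginary parts, each with the target spectrum.
.spectralNoisePair <- function(n, fs, weight) {
  nf <- stats::nextn(n, c(2, 3, 5))
  kMax <- floor((nf - 1) / 2)
  if (kMax < 1L) return(matrix(0, n, 2))
  f <- (1:kMax) * fs / nf
  w <- weight(f) * nf / n
  X <- complex(nf)
  sel <- which(w > 0)
  if (length(sel)) {
    s <- sqrt(2 * w[sel])
    X[sel + 1L] <- complex(real = stats::rnorm(length(sel), sd = s),
                           imaginary = stats::rnorm(length(sel), sd = s))
  }
  x <- stats::fft(X, inverse = TRUE) / sqrt(nf)
  cbind(Re(x)[seq_len(n)], Im(x)[seq_len(n)])
}

# Latent relaxation trajectory at sample resolution: baseline during the
# pre-rest, a linear ramp to rTrue over the first half of the viewing, then a
# plateau held through the post-rest.
.rTrajectory <- function(nPre, nWatch, nPost, rTrue) {
  ramp <- max(1L, floor(nWatch / 2))
  c(rep(.R_BASELINE, nPre),
    .R_BASELINE + (rTrue - .R_BASELINE) * pmin(seq_len(nWatch) / ramp, 1),
    rep(rTrue, nPost))
}

# Join sequential noise pieces with an equal-power (cos/sin) crossfade of
# nX samples; adjacent pieces share the same spectrum at the seam, so the
# joined process keeps its variance and has no discontinuity.
.concatCrossfade <- function(pieces, nX) {
  total <- sum(lengths(pieces)) - nX * (length(pieces) - 1L)
  out <- numeric(total)
  th <- (seq_len(nX) - 0.5) / nX * (pi / 2)
  wIn <- sin(th); wOut <- cos(th)
  pos <- 0L
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    tl <- length(p)
    if (i > 1L) p[seq_len(nX)] <- p[seq_len(nX)] * wIn
    if (i < length(pieces)) p[(tl - nX + 1L):tl] <- p[(tl - nX + 1L):tl] * wOut
    out[(pos + 1L):(pos + tl)] <- out[(pos + 1L):(pos + tl)] + p
    pos <- pos + tl - nX
  }
  out
}

# Synthesize one session (all channels). bandLog: named per-band log power
# at the reference R-state for this participant/segment (incl. jitters).
# The session is piecewise stationary - pre-rest at the baseline R-state,
# the first-half-of-viewing ramp, and the plateau held through the
# post-rest - so the two constant-r intervals are synthesized in a single
# spectral pass each; only the ramp needs per-band envelope modulation.
.synthSession <- function(nPre, nWatch, nPost, fs, rTrue, bandLog,
                          slopes, asymSlope, noiseFloor, nChannels = 3L) {
  n <- nPre + nWatch + nPost
  gen <- canonicalBands()
  isAlpha <- gen$name %in% c("alpha_l", "alpha_h")
  nRamp <- max(1L, floor(nWatch / 2))
  nX <- min(round(fs / 2), nRamp, nPre)   # crossfade length
  out <- matrix(0, n, nChannels)
  pinkPower <- noiseFloor * sum(exp(bandLog))
  # Per-bin weights carrying total variance P over a relative density d(f):
  # w_k = P * len * d_k / (2 * sum(d)), since var(x) = (2/len) * sum(w).
  bandWeight <- function(f, b, P, len) {
    sel <- f >= gen$f_lo[b] & f <= gen$f_hi[b]
    w <- numeric(length(f))
    m <- sum(sel)
    if (m) w[sel] <- P * len / (2 * m)
    w
  }
  # Draw pool: equal-spectrum draws (same length and weight key) are
  # generated two at a time by .spectralNoisePair and handed out singly,
  # roughly halving the number of inverse FFTs.
  pool <- new.env(parent = emptyenv())
  draw <- function(len, key, weightFn) {
    k <- paste0(len, "|", key)
    got <- pool[[k]]
    if (!is.null(got)) {
      pool[[k]] <- NULL
      return(got)
    }
    m <- .spectralNoisePair(len, fs, weightFn)
    pool[[k]] <- m[, 2]
    m[, 1]
  }
  for (ch in seq_len(nChannels)) {
    asymSign <- c(-0.5, 0, 0.5)[ch]  # FP1, FPZ, FP2
    chSlopes <- slopes + ifelse(isAlpha, asymSign * asymSlope, 0)
    static <- chSlopes == 0
    logPowAt <- function(r) bandLog + chSlopes * (r - .R_REFERENCE)
    bankWeight <- function(lp, len, use = seq_len(nrow(gen))) {
      force(lp); force(len); force(use)
      function(f) {
        w <- numeric(length(f))
        for (b in use) w <- w + bandWeight(f, b, exp(lp[b]), len)
        selP <- f >= 0.5 & f <= 50
        if (any(selP) && pinkPower > 0) {
          dens <- 1 / f[selP]
          w[selP] <- w[selP] + pinkPower * len * dens / (2 * sum(dens))
        }
        w
      }
    }
    # stationary piece: all bands at fixed r, plus the pink floor
    constPiece <- function(len, r) {
      lp <- logPowAt(r)
      draw(len, paste0("const|", paste(signif(lp, 12), collapse = ",")),
           bankWeight(lp, len))
    }
    # ramp piece: static bands + pink in one pass, dynamic bands enveloped
    rampPiece <- function(len) {
      x <- draw(len, paste0("rampstatic|", paste(which(static), collapse = ","),
                            "|", paste(signif(bandLog[static], 12),
                                       collapse = ",")),
                bankWeight(bandLog, len, use = which(static)))
      rr <- .R_BASELINE + (rTrue - .R_BASELINE) * pmin(seq_len(len) / nRamp, 1)
      for (b in which(!static)) {
        xb <- draw(len, paste0("unitband|", b),
                   local({
                     bb <- b
                     function(f) bandWeight(f, bb, 1, len)
                   }))
        x <- x + xb * exp(0.5 * (bandLog[b] + chSlopes[b] * (rr - .R_REFERENCE)))
      }
      x
    }
    pieces <- list(constPiece(nPre + nX, .R_BASELINE),
                   rampPiece(nRamp + nX),
                   constPiece(n - nPre - nRamp, rTrue))
    out[, ch] <- .concatCrossfade(pieces, nX)
  }
  out
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-segment latent R-states, assigns three scenes per participant
#' without replacement, synthesizes each session as a sum of band-limited
#' Gaussian components over a pink-noise floor (band log powers following
#' the latent relaxation trajectory with the configured slopes), rounds
#' noisy reported labels into 1-9, and flags `round(dropout * n)` segments
#' unusable.
#'
#' @param config A [SynthConfig-class].
#' @return A list with `recordings` (list of [EegRecording-class]), `labels`
#'   (`data.frame`, one row per segment: identifiers, `r_state_true`,
#'   reported `r_state`, SAM `valence`/`arousal`/`dominance`, `usable`),
#'   and `config`.
#' @examples
#' exp <- generateExperiment(synthConfig(nParticipants = 2, seed = 42))
#' exp$labels
#' @export
generateExperiment <- function(config) {
  validObject(config)
  if (nrow(config@scenes) < 3L)
    stop("configuration error: fewer than 3 scenes configured", call. = FALSE)
  .withSeed(config@seed, {
    fs <- config@fs
    nP <- config@nParticipants
    pid <- sprintf("P%02d", seq_len(nP))
    segs <- do.call(rbind, lapply(seq_len(nP), function(i) {
      sc <- config@scenes[sample.int(nrow(config@scenes), 3L), , drop = FALSE]
      data.frame(participant_id = pid[i], scene = sc$name,
                 duration_s = sc$duration_s, stringsAsFactors = FALSE)
    }))
    m <- nrow(segs)
    segs$segment_id <- sprintf("%s_seg%d", segs$participant_id,
                               stats::ave(seq_len(m), segs$participant_id,
                                          FUN = seq_along))
    rTrue <- .clip(stats::rnorm(m, 6.5, 1.5), 1, 9)
    rRep <- .clip(round(rTrue + stats::rnorm(m, 0, config@labelNoiseSd)), 1, 9)
    valence <- .clip(round(2 + 0.7 * rTrue + stats::rnorm(m, 0, 0.7)), 1, 9)
    arousal <- .clip(round(9.5 - 0.7 * rTrue + stats::rnorm(m, 0, 0.7)), 1, 9)
    dominance <- .clip(round(5 + stats::rnorm(m, 0, 1)), 1, 9)
    nDrop <- round(config@segmentDropout * m)
    usable <- rep(TRUE, m)
    if (nDrop > 0) usable[sample.int(m, nDrop)] <- FALSE

    gain <- stats::rnorm(nP, 0, .SD_PARTICIPANT_GAIN)
    bandOff <- matrix(stats::rnorm(nP * length(.BASE_LOG_POWER), 0,
                                   .SD_PARTICIPANT_BAND), nP)
    nPre <- round(config@restDurationS * fs)
    recordings <- vector("list", m)
    for (j in seq_len(m)) {
      i <- match(segs$participant_id[j], pid)
      segJit <- stats::rnorm(length(.BASE_LOG_POWER), 0, .SD_SEGMENT_BAND)
      bandLog <- .BASE_LOG_POWER + gain[i] + bandOff[i, ] + segJit
      nWatch <- round(segs$duration_s[j] * fs)
      x <- .synthSession(nPre, nWatch, nPre, fs, rTrue[j], bandLog,
                         config@bandResponse, config@asymmetryResponse,
                         config@noiseFloor, length(config@channels))
      colnames(x) <- config@channels
      recordings[[j]] <- new("EegRecording",
        participantId = segs$participant_id[j], sceneId = segs$scene[j],
        segmentId = segs$segment_id[j], fs = fs, channels = config@channels,
        samples = x, watchStart = nPre, watchEnd = nPre + nWatch,
        usable = usable[j])
    }
    names(recordings) <- segs$segment_id
    labels <- data.frame(segment_id = segs$segment_id,
                         participant_id = segs$participant_id,
                         scene = segs$scene,
                         r_state_true = rTrue, r_state = as.numeric(rRep),
                         valence = as.numeric(valence),
                         arousal = as.numeric(arousal),
                         dominance = as.numeric(dominance),
                         usable = usable, stringsAsFactors = FALSE)
    list(recordings = recordings, labels = labels, config = config)
  })
}
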