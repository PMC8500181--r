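#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Configuration of a synthetic relaxation-viewing EEG experiment
#'
#' A `SynthConfig` describes one simulated cohort: how many participants,
#' which scenes (and their durations), the sampling rate and montage, how
#' strongly each frequency band's log power responds to the latent relaxation
#' state (R-state), the hemispheric alpha asymmetry response, noise levels,
#' label noise and segment dropout. Identical configurations with identical
#' seeds produce bit-identical cohorts.
#'
#' @slot nParticipants Number of participants in the cohort.
#' @slot scenes `data.frame` with columns `name` and `duration_s`; every
#'   participant views three scenes drawn without replacement.
#' @slot fs Sampling rate in Hz.
#' @slot channels Ordered channel names (canonically FP1, FPZ, FP2).
#' @slot restDurationS Eyes-open rest before and after each viewing, seconds.
#' @slot bandResponse Named numeric: slope of log band power per unit R-state
#'   for each canonical band (missing bands default to 0).
#' @slot asymmetryResponse Slope of the right-minus-left (FP2 - FP1) alpha
#'   log-power difference per unit R-state.
#' @slot noiseFloor Broadband pink-noise power relative to the summed
#'   reference band power.
#' @slot labelNoiseSd SD of the reported R-state around the latent value.
#' @slot segmentDropout Fraction of segments flagged unusable.
#' @slot seed Integer master seed.
#' @seealso [synthConfig()], [generateExperiment()]
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    nParticipants = "integer", scenes = "data.frame", fs = "numeric",
    channels = "character", restDurationS = "numeric",
    bandResponse = "numeric", asymmetryResponse = "numeric",
    noiseFloor = "numeric", labelNoiseSd = "numeric",
    segmentDropout = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@nParticipants < 1L) msgs <- c(msgs, "nParticipants must be >= 1")
  if (!all(c("name", "duration_s") %in% names(object@scenes)))
    msgs <- c(msgs, "scenes must have columns 'name' and 'duration_s'")
  else {
    if (nrow(object@scenes) < 3L)
      msgs <- c(msgs, "at least 3 scenes must be configured")
    if (any(object@scenes$duration_s < 90))
      msgs <- c(msgs, "scene durations must be >= 90 s")
  }
  if (object@fs <= 0) msgs <- c(msgs, "fs must be > 0")
  if (!all(is.finite(object@bandResponse)) || !is.finite(object@asymmetryResponse))
    msgs <- c(msgs, "all response slopes must be finite")
  if (object@segmentDropout < 0 || object@segmentDropout >= 1)
    msgs <- c(msgs, "segmentDropout must be in [0, 1)")
  if (object@restDurationS <= 0) msgs <- c(msgs, "restDurationS must be > 0")
  if (object@noiseFloor < 0) msgs <- c(msgs, "noiseFloor must be >= 0")
  if (object@labelNoiseSd < 0) msgs <- c(msgs, "labelNoiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' One participant-scene EEG session
#'
#' Samples are microvolts, one column per channel in canonical FP1, FPZ, FP2
#' order. `watchStart`/`watchEnd` are 0-based sample offsets delimiting the
#' half-open viewing interval `[watchStart, watchEnd)`; the samples before
#' and after are the pre- and post-viewing rests.
#'
#' @slot participantId,sceneId,segmentId Identifiers.
#' @slot fs Sampling rate in Hz.
#' @slot channels Ordered channel names.
#' @slot samples Numeric matrix, samples x channels, in microvolts.
#' @slot watchStart,watchEnd 0-based sample markers of the viewing window.
#' @slot usable Whether the segment passed quality screening.
#' @exportClass EegRecording
setClass("EegRecording",
  representation(
    participantId = "character", sceneId = "character", segmentId = "character",
    fs = "numeric", channels = "character", samples = "matrix",
    watchStart = "numeric", watchEnd = "numeric", usable = "logical"))

setValidity("EegRecording", function(object) {
  msgs <- character()
  n <- nrow(object@samples)
  if (ncol(object@samples) != length(object@channels))
    msgs <- c(msgs, "samples must have one column per channel")
  if (length(object@channels) != 3L ||
      !identical(toupper(object@channels), .CANONICAL_CHANNELS))
    msgs <- c(msgs, "channels must be exactly FP1, FPZ, FP2 in canonical order")
  if (!(object@watchStart >= 0 && object@watchStart < object@watchEnd &&
        object@watchEnd <= n))
    msgs <- c(msgs, "markers must satisfy 0 <= watchStart < watchEnd <= n_samples")
  if (object@fs <= 0) msgs <- c(msgs, "fs must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' The four analysis sections of one viewing
#'
#' Holds the aligned `pre`, `begin`, `end` and `post` sections cut from one
#' session: the last `sectionLengthS` seconds of the pre-viewing rest, the
#' first and last `sectionLengthS` seconds of the viewing itself, and the
#' first `sectionLengthS` seconds of the post-viewing rest. All four matrices
#' have identical dimensions. `overlapS` records by how many seconds `begin`
#' and `end` overlap (0 unless the viewing is shorter than twice the section
#' length).
#'
#' @exportClass SectionSet
setClass("SectionSet",
  representation(
    pre = "matrix", begin = "matrix", end = "matrix", post = "matrix",
    fs = "numeric", sectionLengthS = "numeric", overlapS = "numeric",
    participantId = "character", segmentId = "character"))

setValidity("SectionSet", function(object) {
  d <- dim(object@pre)
  if (!identical(d, dim(object@begin)) || !identical(d, dim(object@end)) ||
      !identical(d, dim(object@post)))
    return("all four sections must have identical dimensions")
  TRUE
})

#' Feature table: fragments or sections by named spectral features
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features as rows and
#' fragments (or sections) as columns. `rowData` decodes each feature name
#' into its family, band(s) and channel; `colData` carries participant,
#' segment, section/fragment indices and the R-state and SAM labels.
#'
#' @seealso [buildFeatureTable()], [featureMatrix()], [featureKeySet()]
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

#' Specification of a single base regressor
#'
#' `name` is one of `"LR"` (linear regression), `"SVM"` (RBF support-vector
#' regression), `"RFR"` (random forest), `"AdaBoost"` (AdaBoost.R2 over
#' depth-limited trees), `"Bagging"` (bootstrap-aggregated trees), `"GB"`
#' (depth-3 gradient boosting), `"XGB"` (extreme gradient boosting) or
#' `"LGBM"` (leaf-wise histogram gradient boosting). Unspecified
#' hyperparameters take the documented defaults.
#'
#' @exportClass EstimatorSpec
setClass("EstimatorSpec",
  representation(name = "character", hyperparameters = "list", seed = "integer"))

setValidity("EstimatorSpec", function(object) {
  if (!object@name %in% .ESTIMATOR_NAMES)
    return(sprintf("unknown estimator '%s' (expected one of %s)",
                   object@name, paste(.ESTIMATOR_NAMES, collapse = ", ")))
  TRUE
})

.ESTIMATOR_NAMES <- c("LR", "SVM", "RFR", "AdaBoost", "Bagging", "GB", "XGB", "LGBM")

#' Two-level stacking configuration
#'
#' At least two base regressors at the first level and a simple meta model
#' (`LR` or `SVM`) at the second. `scheme` selects how the stack is
#' cross-validated: `"nested"` (inner leave-one-subject-out inside every
#' outer training set; no leakage) or `"single_loop"` (a single
#' leave-one-subject-out loop whose across-fold average base predictions
#' feed the meta model; optimistically biased, see the vignette).
#'
#' @exportClass StackingSpec
setClass("StackingSpec",
  representation(base = "list", meta = "EstimatorSpec", scheme = "character"))

setValidity("StackingSpec", function(object) {
  msgs <- character()
  if (length(object@base) < 2L) msgs <- c(msgs, "need >= 2 base estimators")
  if (!all(vapply(object@base, is, TRUE, class2 = "EstimatorSpec")))
    msgs <- c(msgs, "base must be a list of EstimatorSpec")
  if (!object@meta@name %in% c("LR", "SVM"))
    msgs <- c(msgs, "meta model must be LR or SVM")
  if (!object@scheme %in% c("nested", "single_loop"))
    msgs <- c(msgs, "scheme must be 'nested' or 'single_loop'")
  if (length(msgs)) msgs else TRUE
})

#' Leave-one-subject-out cross-validation result
#'
#' Stores fold membership (one fold per participant), the out-of-fold
#' prediction for every fragment, per-fold MAE and ACC, and their means
#' across folds.
#'
#' @exportClass CVResult
setClass("CVResult",
  representation(
    folds = "list", predictions = "numeric", labels = "numeric",
    participants = "character", segmentIds = "character",
    foldMae = "numeric", foldAcc = "numeric",
    meanMae = "numeric", meanAcc = "numeric",
    config = "list", seed = "integer"))

setValidity("CVResult", function(object) {
  n <- length(object@predictions)
  idx <- sort(unlist(object@folds, use.names = FALSE))
  if (!identical(idx, seq_len(n)))
    return("folds must partition the prediction vector exactly once")
  if (length(object@labels) != n || length(object@participants) != n)
    return("labels/participants must align with predictions")
  TRUE
})

#' A fitted two-level stacking regressor ready for new cohorts
#'
#' Base models are fitted on the full training table; the meta model is
#' fitted on pooled out-of-fold base predictions so that it never sees its
#' own training residuals. `featureNames` freezes the training feature
#' dictionary; [predictNewCohort()] refuses tables whose columns differ.
#'
#' @exportClass RStack
setClass("RStack",
  representation(
    baseFits = "list", spec = "StackingSpec", metaFit = "list",
    featureNames = "character", trainInfo = "list"))
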