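#' @name accessors
#' @title Accessors for relaxEEG objects
#' @description Small accessor generics: `samplingRate()` and
#'   `channelNames()` for recordings and section sets, `eegSamples()` for the
#'   microvolt sample matrix, `watchWindow()` for the 0-based half-open
#'   viewing markers, `isUsable()` for the quality flag, `sectionMatrix()`
#'   for one of the four analysis sections, `featureMatrix()` for the
#'   (rows = fragments) x (columns = features) numeric matrix of a
#'   [FeatureTable], `featureInfo()`/`fragmentInfo()` for its row and column
#'   annotations, and `predictions()`, `foldMetrics()`, `meanAcc()`,
#'   `meanMae()` for [CVResult] objects.
#' @param object,x An object.
#' @param which For `sectionMatrix()`, one of `"pre"`, `"begin"`, `"end"`,
#'   `"post"`.
#' @return See the individual descriptions.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("eegSamples", function(object) standardGeneric("eegSamples"))
#' @rdname accessors
#' @export
setGeneric("watchWindow", function(object) standardGeneric("watchWindow"))
#' @rdname accessors
#' @export
setGeneric("isUsable", function(object) standardGeneric("isUsable"))
#' @rdname accessors
#' @export
setGeneric("sectionMatrix", function(object, which) standardGeneric("sectionMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))
#' @rdname accessors
#' @export
setGeneric("fragmentInfo", function(object) standardGeneric("fragmentInfo"))
#' @rdname accessors
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))
#' @rdname accessors
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))
#' @rdname accessors
#' @export
setGeneric("meanAcc", function(object) standardGeneric("meanAcc"))
#' @rdname accessors
#' @export
setGeneric("meanMae", function(object) standardGeneric("meanMae"))

#' @rdname accessors
setMethod("samplingRate", "EegRecording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SectionSet", function(object) object@fs)
#' @rdname accessors
setMethod("channelNames", "EegRecording", function(object) object@channels)
#' @rdname accessors
setMethod("eegSamples", "EegRecording", function(object) object@samples)
#' @rdname accessors
setMethod("watchWindow", "EegRecording",
  function(object) c(watchStart = object@watchStart, watchEnd = object@watchEnd))
#' @rdname accessors
setMethod("isUsable", "EegRecording", function(object) object@usable)

#' @rdname accessors
setMethod("sectionMatrix", "SectionSet", function(object, which) {
  which <- match.arg(which, c("pre", "begin", "end", "post"))
  slot(object, which)
})

#' @rdname accessors
setMethod("featureMatrix", "FeatureTable", function(object) {
  t(SummarizedExperiment::assay(object, "features"))
})
#' @rdname accessors
setMethod("featureInfo", "FeatureTable", function(object) {
  as.data.frame(SummarizedExperiment::rowData(object))
})
#' @rdname accessors
setMethod("fragmentInfo", "FeatureTable", function(object) {
  as.data.frame(SummarizedExperiment::colData(object))
})

#' @rdname accessors
setMethod("predictions", "CVResult", function(object) {
  data.frame(participant_id = object@participants,
             segment_id = object@segmentIds,
             r_state = object@labels,
             predicted = object@predictions,
             stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("foldMetrics", "CVResult", function(object) {
  data.frame(participant_id = names(object@foldMae),
             mae = unname(object@foldMae),
             acc = unname(object@foldAcc),
             stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("meanAcc", "CVResult", function(object) object@meanAcc)
#' @rdname accessors
setMethod("meanMae", "CVResult", function(object) object@meanMae)

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nParticipants, "participants,",
      nrow(object@scenes), "scenes, fs =", object@fs, "Hz\n")
  cat("  rest:", object@restDurationS, "s; dropout:", object@segmentDropout,
      "; label noise sd:", object@labelNoiseSd, "; seed:", object@seed, "\n")
  nz <- object@bandResponse[object@bandResponse != 0]
  cat("  band response:",
      if (length(nz)) paste(names(nz), sprintf("%+.2f", nz), collapse = ", ")
      else "(null: all slopes 0)",
      "; alpha asymmetry:", sprintf("%+.2f", object@asymmetryResponse), "\n")
})

setMethod("show", "EegRecording", function(object) {
  cat(sprintf("EegRecording %s (%s / %s): %d samples x %d channels @ %g Hz (%.1f s)\n",
              object@segmentId, object@participantId, object@sceneId,
              nrow(object@samples), ncol(object@samples), object@fs,
              nrow(object@samples) / object@fs))
  cat(sprintf("  viewing [%d, %d) samples = [%.1f, %.1f) s; usable: %s\n",
              object@watchStart, object@watchEnd,
              object@watchStart / object@fs, object@watchEnd / object@fs,
              object@usable))
})

setMethod("show", "SectionSet", function(object) {
  cat(sprintf("SectionSet %s: pre/begin/end/post, %g s each @ %g Hz",
              object@segmentId, object@sectionLengthS, object@fs))
  if (object@overlapS > 0)
    cat(sprintf(" (begin/end overlap %g s)", object@overlapS))
  cat("\n")
})

setMethod("show", "EstimatorSpec", function(object) {
  hp <- object@hyperparameters
  cat(sprintf("EstimatorSpec %s (seed %d)%s\n", object@name, object@seed,
              if (length(hp)) paste0(": ", paste(names(hp), unlist(hp),
                                                 sep = "=", collapse = ", "))
              else ""))
})

setMethod("show", "StackingSpec", function(object) {
  cat(sprintf("StackingSpec [%s] -> %s (scheme: %s)\n",
              paste(vapply(object@base, slot, "", "name"), collapse = ", "),
              object@meta@name, object@scheme))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds (leave-one-subject-out), %d predictions\n",
              length(object@folds), length(object@predictions)))
  cat(sprintf("  mean MAE = %.5f, mean ACC = %.5f\n",
              object@meanMae, object@meanAcc))
})

setMethod("show", "RStack", function(object) {
  cat(sprintf("RStack: %d base models [%s], meta %s, %d features\n",
              length(object@baseFits),
              paste(vapply(object@spec@base, slot, "", "name"), collapse = ", "),
              object@spec@meta@name, length(object@featureNames)))
})
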