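# Assembling per-second features into section- or fragment-level tables.

# Band-decomposed, front-end-filtered slice [from, to) (0-based samples) of a
# recording. Filtering runs on a margin-padded stretch so filter transients
# stay outside the returned rows.
.filteredBandSlice <- function(rec, from, to, bands, marginS = 2,
                               frontOrder = 6) {
  fs <- rec@fs
  n <- nrow(rec@samples)
  pad <- round(marginS * fs)
  m0 <- max(0, from - pad)
  m1 <- min(n, to + pad)
  y <- bandpassFilter(rec@samples[(m0 + 1):m1, , drop = FALSE], fs,
                      order = frontOrder, arPad = FALSE)
  bs <- decomposeBands(y, fs, bands, arPad = FALSE)
  rows <- (from - m0 + 1):(to - m0)
  lapply(bs, function(b) b[rows, , drop = FALSE])
}

.sectionNames <- c("pre", "begin", "end", "post")

#' Build a feature table from recordings
#'
#' At `level = "section"` each usable segment contributes one row per
#' analysis section (pre / begin / end / post, `sectionLengthS` seconds)
#' and every feature is computed directly on the whole section (energy
#' entropy over 1-second sub-windows, AR spectrum fitted to the full
#' section) — the granularity at which viewing contrasts are tested. At
#' `level = "fragment"` features are computed on consecutive 1-second
#' epochs of the last `modelLengthS` seconds of the viewing, the window
#' (`windowS` seconds, advanced by `stepS`; `N = (L - W)/step + 1`
#' fragments per segment) is slid over the epochs, and each fragment's row
#' is the mean of the per-second features it spans.
#'
#' Segments flagged unusable are dropped; at fragment level segments
#' without an R-state label are also dropped (counts are messaged).
#'
#' @param recordings List of [EegRecording-class] objects.
#' @param labels `data.frame` as produced by [generateExperiment()] (at
#'   minimum `segment_id`; label columns are carried through when present).
#' @param level `"fragment"` or `"section"`.
#' @param featureSet `"model"` (147 columns), `"stats"` (174) or `"all"`.
#' @param sectionLengthS Section length for `level = "section"` (s).
#' @param modelLengthS Length of the end-of-viewing window used at fragment
#'   level (s), 30 or 60 in the standard enhancement groups.
#' @param windowS,stepS Fragment window and step (s).
#' @param bands Band definitions (see [canonicalBands()]).
#' @param eeSubwindowS Sub-window for the energy entropy (s); `NULL`
#'   (default) uses 1 s at section level and 0.125 s inside the 1-s model
#'   epochs.
#' @param sections Which sections to compute at `level = "section"`
#'   (default all four); restricting to the sections a contrast needs
#'   saves proportional compute.
#' @return A [FeatureTable-class].
#' @export
buildFeatureTable <- function(recordings, labels,
                              level = c("fragment", "section"),
                              featureSet = c("model", "stats", "all"),
                              sectionLengthS = 30, modelLengthS = 30,
                              windowS = 2, stepS = 1,
                              bands = canonicalBands(),
                              eeSubwindowS = NULL,
                              sections = .sectionNames) {
  level <- match.arg(level)
  featureSet <- match.arg(featureSet)
  sections <- match.arg(sections, .sectionNames, several.ok = TRUE)
  if (is.null(eeSubwindowS))
    eeSubwindowS <- if (level == "section") 1 else 0.125
  keys <- featureKeySet(bands$name, set = featureSet)
  if (is.null(names(recordings)))
    names(recordings) <- vapply(recordings, slot, "", "segmentId")
  keep <- vapply(recordings, isUsable, TRUE)
  if (any(!keep))
    message(sum(!keep), " unusable segment(s) excluded")
  recordings <- recordings[keep]
  labIdx <- match(names(recordings), labels$segment_id)
  if (anyNA(labIdx))
    stop("labels missing for segment(s): ",
         paste(names(recordings)[is.na(labIdx)], collapse = ", "), call. = FALSE)
  lab <- labels[labIdx, , drop = FALSE]
  if (level == "fragment" && "r_state" %in% names(lab)) {
    noLab <- is.na(lab$r_state)
    if (any(noLab)) {
      message(sum(noLab), " segment(s) without R-state label excluded")
      recordings <- recordings[!noLab]
      lab <- lab[!noLab, , drop = FALSE]
    }
  }
  if (!length(recordings)) stop("no usable labeled segments", call. = FALSE)

  labCols <- intersect(c("participant_id", "scene", "r_state_true", "r_state",
                         "valence", "arousal", "dominance"), names(lab))
  blocks <- vector("list", length(recordings))
  meta <- vector("list", length(recordings))
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    fs <- rec@fs
    if (level == "section") {
      L <- round(sectionLengthS * fs)
      ws <- rec@watchStart; we <- rec@watchEnd
      if (ws < L || nrow(rec@samples) - we < L)
        stop("insufficient data: rest shorter than the section length in ",
             rec@segmentId, call. = FALSE)
      secBands <- list()
      fillPair <- function(anchor, first, second) {
        wantF <- first %in% sections; wantS <- second %in% sections
        from <- anchor - if (wantF) L else 0
        to <- anchor + if (wantS) L else 0
        b <- .filteredBandSlice(rec, from, to, bands)
        if (wantF)
          secBands[[first]] <<- lapply(b, function(x) x[1:L, , drop = FALSE])
        if (wantS) {
          off <- if (wantF) L else 0L
          secBands[[second]] <<- lapply(b, function(x)
            x[(off + 1):(off + L), , drop = FALSE])
        }
      }
      if (any(c("pre", "begin") %in% sections)) fillPair(ws, "pre", "begin")
      if (any(c("end", "post") %in% sections)) fillPair(we, "end", "post")
      vals <- vapply(sections, function(sec) {
        # one epoch spanning the whole section: features at section scale
        ep <- .epochFeatureBlock(secBands[[sec]][[1]], fs, keys, bands,
                                 rec@channels, epochS = sectionLengthS,
                                 eeSubwindowS = eeSubwindowS,
                                 bandSignals = secBands[[sec]])
        ep[1L, ]
      }, numeric(nrow(keys)))
      if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(sections))
      blocks[[s]] <- vals  # features x sections
      meta[[s]] <- data.frame(segment_id = rec@segmentId,
                              section = sections,
                              lab[s, labCols, drop = FALSE],
                              row.names = NULL, stringsAsFactors = FALSE)
    } else {
      M <- round(modelLengthS * fs)
      we <- rec@watchEnd
      if (we - rec@watchStart < M)
        stop("viewing shorter than modelLengthS in ", rec@segmentId,
             call. = FALSE)
      bm <- .filteredBandSlice(rec, we - M, we, bands)
      ep <- .epochFeatureBlock(bm[[1]], fs, keys, bands, rec@channels,
                               eeSubwindowS = eeSubwindowS, bandSignals = bm)
      nFrag <- fragmentCount(modelLengthS, windowS, stepS)
      if (nFrag == 0L) stop("window longer than the model segment", call. = FALSE)
      W <- round(windowS); S <- round(stepS)
      frag <- vapply(seq_len(nFrag), function(i) {
        colMeans(ep[((i - 1) * S + 1):((i - 1) * S + W), , drop = FALSE])
      }, numeric(nrow(keys)))
      blocks[[s]] <- frag  # features x nFrag
      meta[[s]] <- data.frame(segment_id = rec@segmentId,
                              fragment_index = seq_len(nFrag),
                              t_start_s = (seq_len(nFrag) - 1) * stepS,
                              lab[s, labCols, drop = FALSE],
                              row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  assay <- do.call(cbind, blocks)
  colData <- do.call(rbind, meta)
  colnames(assay) <- if (level == "section")
    paste(colData$segment_id, colData$section, sep = ".")
  else paste(colData$segment_id, colData$fragment_index, sep = ".")
  rownames(assay) <- keys$name
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    rowData = S4Vectors::DataFrame(keys, row.names = keys$name),
    colData = S4Vectors::DataFrame(colData, row.names = colnames(assay)),
    metadata = list(level = level, featureSet = featureSet,
                    sectionLengthS = sectionLengthS,
                    modelLengthS = modelLengthS,
                    windowS = windowS, stepS = stepS,
                    eeSubwindowS = eeSubwindowS))
  new("FeatureTable", se)
}
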