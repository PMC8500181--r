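# Paired viewing contrasts, significance selection and cross-participant
# consistency.

.CONTRAST_NAMES <- c("begin_end", "pre_post", "pre_end")

#' Define a viewing contrast
#'
#' The three supported contrasts compare section means within each segment:
#' `begin_end` (begin vs end of viewing), `pre_post` (pre-rest vs
#' post-rest), and `pre_end` (pre-rest vs end of viewing). The begin-post
#' comparison is deliberately not offered: early-viewing mood swings and
#' post-viewing decay make it uninterpretable. Deltas are
#' `section_b - section_a`.
#'
#' @param name One of `"begin_end"`, `"pre_post"`, `"pre_end"`.
#' @return List with `name`, `a`, `b`.
#' @export
contrastSpec <- function(name = c("begin_end", "pre_post", "pre_end")) {
  name <- match.arg(name)
  parts <- strsplit(name, "_")[[1]]
  list(name = name, a = parts[1], b = parts[2])
}

#' Paired per-feature tests across a viewing contrast
#'
#' For every feature column, computes the per-segment paired differences
#' `section_b - section_a` and a two-sided paired t-test across segments.
#' Zero-variance difference vectors are reported with the degenerate
#' convention `t = 0`, `p = 1`, `direction = "none"`. The consistency flag
#' is computed at participant level: per-participant segment-averaged
#' deltas must all share one strict sign.
#'
#' @param table A section-level [FeatureTable-class] (see
#'   [buildFeatureTable()] with `level = "section"`).
#' @param contrast A [contrastSpec()] (or contrast name).
#' @return `data.frame` with one row per feature: `feature`, `contrast`,
#'   `t_statistic`, `p_value`, `mean_delta`, `direction`, `n_pairs`,
#'   `consistent`, `degenerate`.
#' @export
pairedContrast <- function(table, contrast = contrastSpec("pre_end")) {
  if (is.character(contrast)) contrast <- contrastSpec(contrast)
  info <- fragmentInfo(table)
  if (!"section" %in% names(info))
    stop("pairedContrast needs a section-level feature table", call. = FALSE)
  mat <- featureMatrix(table)
  selA <- info$section == contrast$a
  selB <- info$section == contrast$b
  segA <- info$segment_id[selA]
  segB <- info$segment_id[selB]
  common <- intersect(segA, segB)
  n <- length(common)
  if (n < 3L) stop("need >= 3 paired segments", call. = FALSE)
  A <- mat[selA, , drop = FALSE][match(common, segA), , drop = FALSE]
  B <- mat[selB, , drop = FALSE][match(common, segB), , drop = FALSE]
  D <- B - A
  md <- colMeans(D)
  sdD <- apply(D, 2, stats::sd)
  tStat <- ifelse(sdD > 0, md / (sdD / sqrt(n)), 0)
  p <- ifelse(sdD > 0, 2 * stats::pt(-abs(tStat), df = n - 1), 1)
  degenerate <- sdD == 0
  direction <- ifelse(degenerate | md == 0, "none",
                      ifelse(md > 0, "increase", "decrease"))
  pid <- info$participant_id[selA][match(common, segA)]
  pidDelta <- rowsum(D, pid) / as.vector(table(pid)[sort(unique(pid))])
  consistent <- vapply(seq_len(ncol(D)), function(j) {
    d <- pidDelta[, j]
    all(d > 0) || all(d < 0)
  }, TRUE)
  data.frame(feature = colnames(mat), contrast = contrast$name,
             t_statistic = unname(tStat), p_value = unname(p),
             mean_delta = unname(md), direction = direction,
             n_pairs = n, consistent = consistent,
             degenerate = unname(degenerate),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select significant contrast results
#'
#' Keeps features with (optionally Benjamini-Hochberg-adjusted) p-value
#' below `alpha`, sorted by ascending p. No correction is applied by
#' default; BH is recommended when the feature bank is screened wholesale.
#'
#' @param results `data.frame` from [pairedContrast()].
#' @param alpha Significance level in (0, 1).
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @return Subset of `results` (with an `adjusted_p` column when
#'   correction is applied), sorted by p-value.
#' @export
selectSignificant <- function(results, alpha = 0.05,
                              correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must be in (0, 1)", call. = FALSE)
  if (!nrow(results)) stop("results must be non-empty", call. = FALSE)
  p <- results$p_value
  if (correction == "benjamini_hochberg") {
    results$adjusted_p <- stats::p.adjust(p, method = "BH")
    keep <- results$adjusted_p < alpha
  } else {
    keep <- p < alpha
  }
  out <- results[keep, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Cross-participant trend consistency
#'
#' A feature's change is consistent when at least `1 - toleranceFrac` of
#' the participants' (segment-averaged) deltas share one strict sign; zero
#' deltas count against consistency. The reported direction is the majority
#' sign regardless of the flag.
#'
#' @param deltas Named numeric, one segment-averaged delta per participant.
#' @param toleranceFrac Allowed fraction of non-conforming participants.
#' @return List with `direction` (`"increase"`, `"decrease"`, `"none"`)
#'   and `consistent` (logical).
#' @export
consistencyTrend <- function(deltas, toleranceFrac = 0) {
  if (length(deltas) < 2L) stop("need >= 2 participants", call. = FALSE)
  fPos <- mean(deltas > 0)
  fNeg <- mean(deltas < 0)
  direction <- if (fPos > fNeg) "increase" else if (fNeg > fPos) "decrease" else "none"
  consistent <- max(fPos, fNeg) >= 1 - toleranceFrac && direction != "none"
  list(direction = direction, consistent = consistent)
}
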