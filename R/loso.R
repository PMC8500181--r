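# Leave-one-subject-out cross-validation and the evaluation metrics.

#' Leave-one-subject-out fold assignment
#'
#' One fold per participant: fold i's test set is every row belonging to
#' participant i, in input order. Fragments of one segment never straddle
#' folds because folds are keyed on the participant.
#'
#' @param participantIds Character/factor vector, one entry per row.
#' @return Named list of integer index vectors (test rows per fold).
#' @export
losoFolds <- function(participantIds) {
  ids <- as.character(participantIds)
  u <- unique(ids)
  if (length(u) < 2L) stop("need >= 2 participants", call. = FALSE)
  stats::setNames(lapply(u, function(p) which(ids == p)), u)
}

#' Mean absolute error
#'
#' `MAE = mean(|y - yhat|)`.
#' @param yTrue,yPred Equal-length numeric vectors.
#' @return Scalar.
#' @examples maeScore(c(5, 8), c(4, 10))  # 1.5
#' @export
maeScore <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || !length(yTrue))
    stop("shape error: lengths must match and be >= 1", call. = FALSE)
  mean(abs(yTrue - yPred))
}

#' Mean relative accuracy
#'
#' `ACC = 1 - mean(|y - yhat| / y)`. Requires strictly positive targets
#' (R-state labels are in 1-9). The value can be negative for predictions
#' worse than 100% relative error; it is not clipped.
#'
#' @param yTrue Positive numeric vector.
#' @param yPred Numeric vector of the same length.
#' @return Scalar, 1 for perfect predictions.
#' @examples accScore(c(5, 8), c(4, 10))  # 0.775
#' @export
accScore <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || !length(yTrue))
    stop("shape error: lengths must match and be >= 1", call. = FALSE)
  if (any(yTrue <= 0)) stop("domain error: yTrue must be > 0", call. = FALSE)
  1 - mean(abs(yTrue - yPred) / yTrue)
}

.modelXy <- function(table) {
  X <- featureMatrix(table)
  info <- fragmentInfo(table)
  if (!"r_state" %in% names(info))
    stop("feature table has no r_state labels", call. = FALSE)
  list(X = X, y = info$r_state, ids = info$participant_id,
       segs = info$segment_id)
}

.cvResult <- function(folds, preds, y, ids, segs, config, seed) {
  foldMae <- vapply(folds, function(ix) maeScore(y[ix], preds[ix]), 0)
  foldAcc <- vapply(folds, function(ix) accScore(y[ix], preds[ix]), 0)
  new("CVResult", folds = folds, predictions = preds, labels = y,
      participants = as.character(ids), segmentIds = as.character(segs),
      foldMae = foldMae, foldAcc = foldAcc,
      meanMae = mean(foldMae), meanAcc = mean(foldAcc),
      config = config, seed = as.integer(seed))
}

#' Evaluate one regressor under leave-one-subject-out cross-validation
#'
#' Fits the estimator on all-but-one participant and predicts the held-out
#' participant's fragments, rotating over all participants. MAE and ACC are
#' computed per fold (per participant) and averaged across folds.
#'
#' @param table A fragment-level [FeatureTable-class] with `r_state` labels.
#' @param estimator An [estimatorSpec()] or estimator name.
#' @return A [CVResult-class].
#' @export
fitPredictLoso <- function(table, estimator) {
  spec <- if (is.character(estimator)) estimatorSpec(estimator) else estimator
  d <- .modelXy(table)
  folds <- losoFolds(d$ids)
  preds <- rep(NA_real_, length(d$y))
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    sub <- spec
    sub@seed <- .subSeed(spec@seed, k)
    fit <- .fitEstimator(sub, d$X[-test, , drop = FALSE], d$y[-test])
    preds[test] <- .predictEstimator(fit, d$X[test, , drop = FALSE])
  }
  .cvResult(folds, preds, d$y, d$ids, d$segs,
            list(estimator = spec@name, hyperparameters = spec@hyperparameters),
            spec@seed)
}

#' Aggregate fragment predictions to segments
#'
#' The segment-level prediction is the arithmetic mean of the segment's
#' fragment predictions.
#'
#' @param result A [CVResult-class].
#' @return `data.frame` with `participant_id`, `segment_id`, `r_state`,
#'   `predicted`.
#' @export
segmentPredictions <- function(result) {
  pr <- predictions(result)
  agg <- stats::aggregate(cbind(r_state, predicted) ~ participant_id + segment_id,
                          data = pr, FUN = mean)
  agg[order(agg$participant_id, agg$segment_id), , drop = FALSE]
}
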