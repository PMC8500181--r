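# Two-level stacking: base regressors' out-of-fold predictions feed a
# simple meta model.

#' Configure a two-level stacking regressor
#'
#' @param base List of estimator names or [EstimatorSpec-class] objects
#'   (default RFR, AdaBoost, GB, LGBM).
#' @param meta Meta model, `"LR"` or `"SVM"`.
#' @param scheme `"nested"` (leakage-free nested leave-one-subject-out,
#'   the default) or `"single_loop"` (single LOSO loop; the meta model is
#'   trained on pooled out-of-fold base predictions and scored on the
#'   across-fold average of base predictions — an optimistic protocol kept
#'   for comparability).
#' @param seed Integer master seed fanned out to per-model, per-fold
#'   sub-seeds.
#' @return A [StackingSpec-class].
#' @export
stackingSpec <- function(base = c("RFR", "AdaBoost", "GB", "LGBM"),
                         meta = "SVM",
                         scheme = c("nested", "single_loop"),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  baseSpecs <- lapply(seq_along(base), function(i) {
    b <- base[[i]]
    if (is(b, "EstimatorSpec")) b
    else estimatorSpec(b, seed = .subSeed(seed, i))
  })
  metaSpec <- if (is(meta, "EstimatorSpec")) meta
              else estimatorSpec(meta, seed = .subSeed(seed, 1000L))
  new("StackingSpec", base = baseSpecs, meta = metaSpec, scheme = scheme)
}

# LOSO out-of-fold predictions for one base spec. When avgAll = TRUE also
# accumulates each fold model's predictions on all rows (their across-fold
# mean), discarding every fitted model immediately to bound memory.
.losoOof <- function(spec, X, y, folds, avgAll = FALSE) {
  oof <- rep(NA_real_, length(y))
  avg <- if (avgAll) numeric(length(y)) else NULL
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    sub <- spec
    sub@seed <- .subSeed(spec@seed, k)
    fit <- .fitEstimator(sub, X[-test, , drop = FALSE], y[-test])
    oof[test] <- .predictEstimator(fit, X[test, , drop = FALSE])
    if (avgAll) avg <- avg + .predictEstimator(fit, X) / length(folds)
  }
  list(oof = oof, avg = avg)
}

#' Cross-validated two-level stacking
#'
#' Under the default `"nested"` scheme each outer leave-one-subject-out
#' fold runs an inner LOSO over its training participants to produce
#' out-of-fold base predictions that train the meta model; the base models
#' are then refit on the full outer training set to predict the held-out
#' participant, whose data therefore never influences any fitted model.
#' The `"single_loop"` scheme runs a single LOSO loop per base model,
#' trains the meta model on the pooled out-of-fold base predictions, and
#' scores every participant on the across-fold average of the base models'
#' predictions; because most fold models saw the scored participant, this
#' protocol is optimistically biased (documented in the vignette).
#'
#' @param table A fragment-level [FeatureTable-class] with `r_state` labels.
#' @param spec A [stackingSpec()].
#' @param keepStack If `TRUE` (and `scheme = "single_loop"`), base models
#'   are additionally refit on the full table and a deployable
#'   [RStack-class] is stored in `result@config$stack`, reusing the
#'   out-of-fold predictions already computed.
#' @return A [CVResult-class]. For the nested scheme,
#'   `result@config$foldTrainRows` records, per outer fold, the row indices
#'   any fitted model saw — the basis of the no-leakage audit.
#' @export
stackFitPredict <- function(table, spec = stackingSpec(), keepStack = FALSE) {
  validObject(spec)
  d <- .modelXy(table)
  folds <- losoFolds(d$ids)
  nB <- length(spec@base)
  preds <- rep(NA_real_, length(d$y))
  extra <- list()
  if (spec@scheme == "nested") {
    allIdx <- seq_along(d$y)
    extra$foldTrainRows <- lapply(folds, function(test) setdiff(allIdx, test))
    for (k in seq_along(folds)) {
      test <- folds[[k]]
      Xtr <- d$X[-test, , drop = FALSE]
      ytr <- d$y[-test]
      innerFolds <- losoFolds(d$ids[-test])
      Z <- matrix(NA_real_, length(ytr), nB)
      Ztest <- matrix(NA_real_, length(test), nB)
      for (b in seq_len(nB)) {
        bs <- spec@base[[b]]
        bs@seed <- .subSeed(bs@seed, 10000L + k)
        Z[, b] <- .losoOof(bs, Xtr, ytr, innerFolds)$oof
        full <- .fitEstimator(bs, Xtr, ytr)
        Ztest[, b] <- .predictEstimator(full, d$X[test, , drop = FALSE])
      }
      ms <- spec@meta
      ms@seed <- .subSeed(ms@seed, k)
      metaFit <- .fitEstimator(ms, Z, ytr)
      preds[test] <- .predictEstimator(metaFit, Ztest)
    }
  } else {
    Z <- matrix(NA_real_, length(d$y), nB)      # out-of-fold base predictions
    Zavg <- matrix(0, length(d$y), nB)          # across-fold average predictions
    for (b in seq_len(nB)) {
      r <- .losoOof(spec@base[[b]], d$X, d$y, folds, avgAll = TRUE)
      Z[, b] <- r$oof
      Zavg[, b] <- r$avg
    }
    metaFit <- .fitEstimator(spec@meta, Z, d$y)
    preds <- .predictEstimator(metaFit, Zavg)
    if (keepStack) {
      baseFits <- lapply(spec@base, function(b) .fitEstimator(b, d$X, d$y))
      extra$stack <- new("RStack", baseFits = baseFits, spec = spec,
                         metaFit = metaFit, featureNames = colnames(d$X),
                         trainInfo = list(nParticipants = length(folds),
                                          n = length(d$y)))
    }
  }
  .cvResult(folds, preds, d$y, d$ids, d$segs,
            c(list(stacking = vapply(spec@base, slot, "", "name"),
                   meta = spec@meta@name, scheme = spec@scheme), extra),
            spec@meta@seed)
}

#' Fit a deployable stacking regressor
#'
#' Trains the meta model on pooled leave-one-subject-out out-of-fold base
#' predictions, then refits every base model on the full table. The
#' resulting object predicts new cohorts via [predictNewCohort()].
#'
#' @param table A fragment-level [FeatureTable-class] with `r_state` labels.
#' @param spec A [stackingSpec()].
#' @return An [RStack-class].
#' @export
fitStack <- function(table, spec = stackingSpec()) {
  validObject(spec)
  d <- .modelXy(table)
  folds <- losoFolds(d$ids)
  nB <- length(spec@base)
  Z <- matrix(NA_real_, length(d$y), nB)
  baseFits <- vector("list", nB)
  for (b in seq_len(nB)) {
    Z[, b] <- .losoOof(spec@base[[b]], d$X, d$y, folds)$oof
    baseFits[[b]] <- .fitEstimator(spec@base[[b]], d$X, d$y)
  }
  metaFit <- .fitEstimator(spec@meta, Z, d$y)
  new("RStack", baseFits = baseFits, spec = spec, metaFit = metaFit,
      featureNames = colnames(d$X),
      trainInfo = list(nParticipants = length(folds), n = length(d$y)))
}

#' Predict the R-state of a new cohort
#'
#' Applies a fitted stack to an unlabeled fragment-level feature table whose
#' columns must match the training feature dictionary exactly. Per-fragment
#' predictions are averaged to one value per segment and the cohort mean is
#' attached.
#'
#' @param stack An [RStack-class] from [fitStack()].
#' @param table A fragment-level [FeatureTable-class] (labels not needed).
#' @return `data.frame` with one row per segment (`participant_id`,
#'   `segment_id`, `n_fragments`, `predicted_r_state`); the cohort mean is
#'   in `attr(, "cohortMean")`.
#' @export
predictNewCohort <- function(stack, table) {
  X <- featureMatrix(table)
  if (!identical(colnames(X), stack@featureNames)) {
    missing <- setdiff(stack@featureNames, colnames(X))
    extra <- setdiff(colnames(X), stack@featureNames)
    stop("schema error: feature columns do not match training dictionary",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  Z <- do.call(cbind, lapply(stack@baseFits, .predictEstimator, newX = X))
  pf <- .predictEstimator(stack@metaFit, Z)
  info <- fragmentInfo(table)
  agg <- stats::aggregate(pf, list(participant_id = info$participant_id,
                                   segment_id = info$segment_id), mean)
  cnt <- stats::aggregate(pf, list(participant_id = info$participant_id,
                                   segment_id = info$segment_id), length)
  out <- data.frame(participant_id = agg$participant_id,
                    segment_id = agg$segment_id,
                    n_fragments = cnt$x,
                    predicted_r_state = agg$x, stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cohortMean") <- mean(out$predicted_r_state)
  out
}
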