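# Two-level stacking: schemes, leakage direction, deployment.

linearTable <- function(n = 60, p = 6, nPart = 6, noise = 0.2, seed = 21) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  y <- pmax(1, pmin(9, 5 + 1.5 * X[, 1] - X[, 2] + rnorm(n, 0, noise)))
  ids <- rep(sprintf("p%d", seq_len(nPart)), each = n / nPart)
  manualFragmentTable(X, ids, y)
}

test_that("stacking specs validate base and meta choices", {
  sp <- stackingSpec()
  expect_equal(vapply(sp@base, slot, "", "name"),
               c("RFR", "AdaBoost", "GB", "LGBM"))
  expect_equal(sp@meta@name, "SVM")
  expect_error(stackingSpec(base = list("LR"), meta = "LR"), "2 base")
  expect_error(stackingSpec(meta = "RFR"), "LR or SVM")
})

test_that("a meta learner passes through agreeing, near-perfect bases", {
  tab <- linearTable(noise = 0.01)
  sp <- stackingSpec(base = c("LR", "LR"), meta = "LR", scheme = "nested")
  cv <- stackFitPredict(tab, sp)
  expect_gt(meanAcc(cv), 0.98)
  expect_lt(meanMae(cv), 0.1)
})

test_that("the meta model leans on the stronger base column", {
  tab <- linearTable(noise = 0.05)
  weakSpec <- estimatorSpec("RFR", list(numTrees = 10), seed = 2)
  cvWeak <- fitPredictLoso(tab, weakSpec)
  sp <- stackingSpec(base = list(estimatorSpec("LR"), weakSpec),
                     meta = "LR", scheme = "nested")
  cvStack <- stackFitPredict(tab, sp)
  expect_lte(meanMae(cvStack), meanMae(cvWeak))
})

test_that("nested stacking never trains on the held-out participant", {
  tab <- linearTable()
  sp <- stackingSpec(base = list(estimatorSpec("LR"),
                                 estimatorSpec("RFR", list(numTrees = 15))),
                     meta = "LR", scheme = "nested")
  cv <- stackFitPredict(tab, sp)
  audit <- cv@config$foldTrainRows
  expect_length(audit, length(cv@folds))
  for (p in names(cv@folds)) {
    expect_length(intersect(cv@folds[[p]], audit[[p]]), 0)
    expect_setequal(c(cv@folds[[p]], audit[[p]]),
                    seq_along(cv@predictions))
  }
  # every fragment predicted exactly once
  expect_false(anyNA(cv@predictions))
  expect_identical(sort(unlist(cv@folds, use.names = FALSE)),
                   seq_along(cv@predictions))
})

test_that("the single-loop scheme is optimistically biased", {
  cmp <- sapply(1:10, function(s) {
    tab <- linearTable(n = 60, nPart = 6, noise = 1.2, seed = 500 + s)
    base <- list(estimatorSpec("RFR", list(numTrees = 20), seed = s),
                 estimatorSpec("LR", seed = s))
    nest <- stackFitPredict(tab, stackingSpec(base, "LR", "nested", seed = s))
    lit <- stackFitPredict(tab, stackingSpec(base, "LR", "single_loop",
                                             seed = s))
    meanAcc(lit) >= meanAcc(nest)
  })
  expect_gte(sum(cmp), 8)
})

test_that("a deployed stack scores new cohorts and validates their schema", {
  tab <- linearTable(n = 120, nPart = 6, noise = 0.1)
  sp <- stackingSpec(base = list(estimatorSpec("LR"),
                                 estimatorSpec("RFR", list(numTrees = 20))),
                     meta = "SVM")
  stack <- fitStack(tab, sp)
  expect_s4_class(stack, "RStack")
  # 22 synthetic patients, one segment each
  set.seed(22)
  Xnew <- matrix(rnorm(22 * 6), 22)
  colnames(Xnew) <- stack@featureNames
  newTab <- manualFragmentTable(Xnew, sprintf("subj%02d", 1:22),
                                rep(5, 22),
                                segments = sprintf("subj%02d_s1", 1:22))
  rep22 <- predictNewCohort(stack, newTab)
  expect_equal(nrow(rep22), 22)
  expect_true(all(c("participant_id", "segment_id", "n_fragments",
                    "predicted_r_state") %in% names(rep22)))
  expect_equal(attr(rep22, "cohortMean"), mean(rep22$predicted_r_state))
  # all-zero features: degenerate but valid
  zeroTab <- manualFragmentTable(matrix(0, 4, 6,
                                        dimnames = list(NULL, stack@featureNames)),
                                 rep("z", 4), rep(5, 4))
  expect_true(all(is.finite(predictNewCohort(stack, zeroTab)$predicted_r_state)))
  # schema mismatch names the offending columns
  bad <- Xnew
  colnames(bad)[1] <- "x_unknown"
  badTab <- manualFragmentTable(bad, sprintf("s%02d", 1:22), rep(5, 22))
  expect_error(predictNewCohort(stack, badTab), "schema error")
})

test_that("fragment predictions average into segment-level cohort reports", {
  tab <- linearTable(n = 80, nPart = 4, noise = 0.1)
  sp <- stackingSpec(base = list(estimatorSpec("LR"), estimatorSpec("LR")),
                     meta = "LR")
  stack <- fitStack(tab, sp)
  info <- fragmentInfo(tab)
  out <- predictNewCohort(stack, tab)
  expect_equal(nrow(out), length(unique(info$segment_id)))
})
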