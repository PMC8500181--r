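# LOSO folds, metrics, single-estimator evaluation.

test_that("LOSO folds partition rows by participant", {
  ids <- rep(sprintf("P%02d", 1:26), each = 3)
  folds <- losoFolds(ids)
  expect_length(folds, 26)
  expect_identical(sort(unlist(folds, use.names = FALSE)), seq_along(ids))
  for (p in names(folds)) expect_true(all(ids[folds[[p]]] == p))
  two <- losoFolds(c("a", "b", "a"))
  expect_equal(two, list(a = c(1L, 3L), b = 2L))
  expect_error(losoFolds(rep("a", 5)), "2 participants")
})

test_that("MAE and ACC reproduce their defining formulas", {
  expect_equal(maeScore(c(5, 8), c(4, 10)), 1.5)
  expect_equal(accScore(c(5, 8), c(4, 10)), 0.775)
  expect_equal(maeScore(1:5, 1:5), 0)
  expect_equal(accScore(1:5, 1:5), 1)
  # constant prediction at the mean of y = (4, 8)
  expect_equal(accScore(c(4, 8), c(6, 6)), 0.625)
  # MAE translation invariance
  set.seed(12)
  y <- runif(20, 1, 9); p <- y + rnorm(20)
  expect_equal(maeScore(y + 3, p + 3), maeScore(y, p), tolerance = 1e-12)
  expect_error(maeScore(1:3, 1:4), "shape")
  expect_error(accScore(c(0, 1), c(1, 1)), "domain")
})

test_that("every estimator recovers a constant target exactly enough", {
  set.seed(13)
  X <- matrix(rnorm(40 * 5), 40)
  tab <- manualFragmentTable(X, rep(c("a", "b", "c", "d"), each = 10),
                             rep(7, 40))
  for (est in c("LR", "SVM", "RFR", "GB", "XGB", "LGBM")) {
    cv <- fitPredictLoso(tab, est)
    expect_lt(meanMae(cv), 0.11, label = paste(est, "MAE"))
    expect_gt(meanAcc(cv), 0.985, label = paste(est, "ACC"))
  }
  cvLR <- fitPredictLoso(tab, "LR")
  expect_lt(meanMae(cvLR), 1e-6)
  expect_gt(meanAcc(cvLR), 1 - 1e-6)
  expect_error(fitPredictLoso(tab, estimatorSpec("RIDGE")), "unknown")
})

test_that("uninformative features cannot beat the train-mean baseline", {
  gain <- sapply(1:10, function(s) {
    set.seed(300 + s)
    n <- 120
    ids <- rep(sprintf("p%d", 1:8), each = 15)
    X <- matrix(rnorm(n * 10), n)
    y <- rep(sample(seq(2, 9, length.out = 8)), each = 15)
    tab <- manualFragmentTable(X, ids, y)
    cv <- fitPredictLoso(tab, estimatorSpec("LGBM", seed = s))
    folds <- losoFolds(ids)
    base <- mean(vapply(folds, function(ix) {
      accScore(y[ix], rep(mean(y[-ix]), length(ix)))
    }, 0))
    meanAcc(cv) - base
  })
  expect_lt(mean(gain), 0.02)
})

test_that("cross-validation results are deterministic under a fixed seed", {
  set.seed(14)
  X <- matrix(rnorm(60 * 8), 60)
  y <- 2 + 3 * X[, 1] + rnorm(60, 0, 0.3) + 4
  ids <- rep(c("a", "b", "c"), each = 20)
  tab <- manualFragmentTable(X, ids, pmax(1, pmin(9, y)))
  for (est in c("RFR", "Bagging", "AdaBoost", "GB", "XGB", "LGBM")) {
    cv1 <- fitPredictLoso(tab, estimatorSpec(est, seed = 5L))
    cv2 <- fitPredictLoso(tab, estimatorSpec(est, seed = 5L))
    expect_identical(cv1@predictions, cv2@predictions, label = est)
  }
})

test_that("reported fold metrics equal metrics recomputed from predictions", {
  set.seed(15)
  X <- matrix(rnorm(60 * 6), 60)
  y <- pmax(1, pmin(9, 5 + X[, 1] + rnorm(60, 0, 0.2)))
  tab <- manualFragmentTable(X, rep(c("a", "b", "c", "d"), each = 15), y)
  cv <- fitPredictLoso(tab, "RFR")
  for (p in names(cv@folds)) {
    ix <- cv@folds[[p]]
    expect_equal(cv@foldMae[[p]], maeScore(cv@labels[ix], cv@predictions[ix]),
                 tolerance = 1e-9)
    expect_equal(cv@foldAcc[[p]], accScore(cv@labels[ix], cv@predictions[ix]),
                 tolerance = 1e-9)
  }
  expect_equal(meanMae(cv), mean(cv@foldMae), tolerance = 1e-12)
  expect_equal(meanAcc(cv), mean(cv@foldAcc), tolerance = 1e-12)
})

test_that("segment aggregation is the exact mean of fragment predictions", {
  set.seed(16)
  X <- matrix(rnorm(40 * 4), 40)
  y <- rep(c(3, 6, 4, 8), each = 10)
  segs <- rep(c("a_s1", "a_s2", "b_s1", "b_s2"), each = 10)
  tab <- manualFragmentTable(X, rep(c("a", "b"), each = 20), y, segs)
  cv <- fitPredictLoso(tab, "LR")
  sp <- segmentPredictions(cv)
  pr <- predictions(cv)
  for (i in seq_len(nrow(sp))) {
    sel <- pr$segment_id == sp$segment_id[i]
    expect_equal(sp$predicted[i], mean(pr$predicted[sel]), tolerance = 1e-12)
  }
})
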