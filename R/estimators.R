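# Regressor backends. Feature standardization (train-fold mean/sd) is
# applied inside the LR and SVM backends; tree ensembles consume raw
# features.

#' Specify a base regressor
#'
#' Known estimators and their defaults:
#' \describe{
#'   \item{LR}{ordinary least squares (rank-deficient columns dropped).}
#'   \item{SVM}{RBF support-vector regression, `cost = 1`,
#'     `epsilon = 0.1`, `gamma = 1/p` ([e1071::svm]).}
#'   \item{RFR}{random forest, `numTrees = 100` ([ranger::ranger]).}
#'   \item{AdaBoost}{AdaBoost.R2 with linear loss over depth-3 trees,
#'     `nEstimators = 100`.}
#'   \item{Bagging}{100 bootstrap-aggregated regression trees
#'     (`maxDepth = 10`).}
#'   \item{GB}{gradient boosting with depth-3 trees, `eta = 0.1`,
#'     `nRounds = 100`.}
#'   \item{XGB}{extreme gradient boosting, depth 6, `eta = 0.1`,
#'     `nRounds = 100` ([xgboost::xgb.train]).}
#'   \item{LGBM}{leaf-wise histogram gradient boosting
#'     (`max_leaves = 31`, `eta = 0.1`, `nRounds = 100`).}
#' }
#'
#' @param name Estimator name (see above).
#' @param hyperparameters Named list overriding the defaults.
#' @param seed Integer seed for the stochastic fits.
#' @return An [EstimatorSpec-class].
#' @export
estimatorSpec <- function(name, hyperparameters = list(), seed = 1L) {
  if (is(name, "EstimatorSpec")) return(name)
  spec <- new("EstimatorSpec", name = name,
              hyperparameters = hyperparameters, seed = as.integer(seed))
  spec@hyperparameters <- utils::modifyList(.defaultHyper(name), hyperparameters)
  spec
}

.defaultHyper <- function(name) {
  switch(name,
    LR = list(),
    SVM = list(cost = 1, epsilon = 0.1),
    RFR = list(numTrees = 100),
    AdaBoost = list(nEstimators = 100, maxDepth = 3, loss = "linear"),
    Bagging = list(nEstimators = 100, maxDepth = 10, cp = 0.002, minsplit = 10),
    GB = list(nRounds = 100, eta = 0.1, maxDepth = 3),
    XGB = list(nRounds = 100, eta = 0.1, maxDepth = 6),
    LGBM = list(nRounds = 100, eta = 0.1, maxLeaves = 31),
    stop("configuration error: unknown estimator '", name, "'", call. = FALSE))
}

.standardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, s = s, X = sweep(sweep(X, 2, mu), 2, s, "/"))
}

.applyStandardize <- function(std, X) sweep(sweep(X, 2, std$mu), 2, std$s, "/")

.rpartFit <- function(X, y, w = NULL, maxDepth = 3, cp = 0, minsplit = 10) {
  df <- as.data.frame(X)
  df$.y <- y
  # no missing values here: skip surrogate/competitor split bookkeeping
  fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = maxDepth, cp = cp, minsplit = minsplit,
                        xval = 0, maxcompete = 0, maxsurrogate = 0,
                        usesurrogate = 0))
  # drop references that pin the training data in memory (the terms
  # environment captures this frame; prediction always gets full newdata)
  attr(fit$terms, ".Environment") <- baseenv()
  fit$where <- NULL
  fit$y <- NULL
  fit$call <- NULL
  fit
}

.rpartPredict <- function(fit, newX) {
  unname(stats::predict(fit, as.data.frame(newX)))
}

# AdaBoost.R2 (Drucker 1997) with linear loss and weighted-median prediction.
.fitAdaBoostR2 <- function(X, y, nEstimators, maxDepth, seed) {
  n <- length(y)
  w <- rep(1 / n, n)
  fits <- list(); betas <- numeric(0)
  .withSeed(seed, {
    for (m in seq_len(nEstimators)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      fit <- .rpartFit(X[idx, , drop = FALSE], y[idx], maxDepth = maxDepth)
      pred <- .rpartPredict(fit, X)
      err <- abs(pred - y)
      D <- max(err)
      if (D == 0) { fits[[m]] <- fit; betas[m] <- 1e-10; break }
      L <- err / D
      ebar <- sum(w * L)
      if (ebar >= 0.5) break
      beta <- ebar / (1 - ebar)
      fits[[m]] <- fit
      betas[m] <- beta
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  if (!length(fits)) {  # first learner already too weak: keep it unweighted
    fit <- .rpartFit(X, y, maxDepth = maxDepth)
    fits <- list(fit); betas <- 1
  }
  list(fits = fits, logInvBeta = log(1 / betas))
}

.predictAdaBoostR2 <- function(model, X) {
  P <- vapply(model$fits, .rpartPredict, numeric(nrow(X)), newX = X)
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
  wts <- model$logInvBeta
  apply(P, 1, function(pr) {
    o <- order(pr)
    cw <- cumsum(wts[o])
    pr[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

# Fit one estimator; returns an opaque fit list consumed by .predictEstimator.
.fitEstimator <- function(spec, X, y) {
  hp <- spec@hyperparameters
  X <- as.matrix(X)
  kind <- spec@name
  fit <- switch(kind,
    LR = {
      std <- .standardize(X)
      beta <- stats::lm.fit(cbind(1, std$X), y)$coefficients
      beta[is.na(beta)] <- 0
      list(std = std, beta = beta)
    },
    SVM = {
      if (stats::sd(y) == 0) {
        # e1071 yields an empty model on constant targets; a constant
        # predictor is the exact solution
        std <- .standardize(X)
        list(std = std, beta = c(y[1], rep(0, ncol(X))), kind = "LR")
      } else {
        std <- .standardize(X)
        list(std = std,
             model = e1071::svm(x = std$X, y = y, type = "eps-regression",
                                kernel = "radial", cost = hp$cost,
                                epsilon = hp$epsilon, scale = FALSE))
      }
    },
    RFR = list(model = ranger::ranger(x = X, y = y, num.trees = hp$numTrees,
                                      num.threads = 1, seed = spec@seed)),
    AdaBoost = .fitAdaBoostR2(X, y, hp$nEstimators, hp$maxDepth, spec@seed),
    Bagging = .withSeed(spec@seed, {
      n <- length(y)
      list(fits = lapply(seq_len(hp$nEstimators), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        .rpartFit(X[idx, , drop = FALSE], y[idx], maxDepth = hp$maxDepth,
                  cp = hp$cp, minsplit = hp$minsplit)
      }))
    }),
    GB = list(model = xgboost::xgb.train(
      params = list(eta = hp$eta, max_depth = hp$maxDepth, nthread = 1,
                    lambda = 0, objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nRounds, verbose = 0)),
    XGB = list(model = xgboost::xgb.train(
      params = list(eta = hp$eta, max_depth = hp$maxDepth, nthread = 1,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nRounds, verbose = 0)),
    LGBM = list(model = xgboost::xgb.train(
      params = list(eta = hp$eta, tree_method = "hist",
                    grow_policy = "lossguide", max_leaves = hp$maxLeaves,
                    max_depth = 0, nthread = 1,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nRounds, verbose = 0)),
    stop("configuration error: unknown estimator '", kind, "'", call. = FALSE))
  c(fit, list(kind = kind))
}

.predictEstimator <- function(fit, newX) {
  X <- as.matrix(newX)
  switch(fit$kind,
    LR = as.vector(cbind(1, .applyStandardize(fit$std, X)) %*% fit$beta),
    SVM = unname(stats::predict(fit$model, .applyStandardize(fit$std, X))),
    RFR = stats::predict(fit$model, data = X, num.threads = 1)$predictions,
    AdaBoost = .predictAdaBoostR2(fit, X),
    Bagging = {
      P <- vapply(fit$fits, .rpartPredict, numeric(nrow(X)), newX = X)
      if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
      rowMeans(P)
    },
    GB = ,
    XGB = ,
    LGBM = unname(stats::predict(fit$model, xgboost::xgb.DMatrix(X))))
}
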