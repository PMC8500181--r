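# Feature bank: closed forms, transformation laws, enumeration, assembly.

test_that("energy matches closed forms and Parseval", {
  t1 <- seq(0, 1 - 1 / 256, by = 1 / 256)
  expect_equal(bandEnergy(sin(2 * pi * 10 * t1)), 128, tolerance = 1e-12)
  expect_equal(bandEnergy(3 * sin(2 * pi * 8 * t1)), 9 * 128,
               tolerance = 1e-12)
  expect_equal(bandEnergy(numeric(5)), 0)
  set.seed(3)
  x <- rnorm(1000)
  expect_equal(bandEnergy(x), sum(abs(fft(x))^2) / length(x),
               tolerance = 1e-9)
  expect_error(bandEnergy(numeric(0)), "length")
})

test_that("energy ratio obeys reciprocity and guards division", {
  expect_equal(energyRatio(3, 3), 1)
  expect_equal(energyRatio(2, 4), 0.5)
  set.seed(4)
  for (i in 1:10) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(energyRatio(a, b) * energyRatio(b, a), 1, tolerance = 1e-12)
  }
  expect_error(energyRatio(1, 0), "division guard")
})

test_that("energy entropy hits its uniform and degenerate bounds", {
  fs <- 8
  expect_equal(energyEntropy(rep(1, 30 * fs), fs), log(30), tolerance = 1e-9)
  concentrated <- c(rep(1, fs), rep(0, 3 * fs))
  expect_equal(energyEntropy(concentrated, fs), 0)
  # p = (0.5, 0.5) in the literal form: 2 * log(0.25)
  expect_equal(energyEntropy(rep(1, 2 * fs), fs, mode = "literal"),
               2 * log(0.25), tolerance = 1e-9)
  expect_error(energyEntropy(rep(0, 4 * fs), fs), "zero total energy")
  expect_error(energyEntropy(rep(1, fs), fs), "two sub-windows")
})

test_that("differential entropy follows the Gaussian closed form", {
  x <- c(0, 2)  # sample variance exactly 2
  expect_equal(differentialEntropy(x), 0.5 * log(2 * pi * exp(1) * 2),
               tolerance = 1e-12)
  set.seed(5)
  z <- rnorm(2000)
  # scaling law: DE(c x) = DE(x) + log|c|
  expect_equal(differentialEntropy(3 * z), differentialEntropy(z) + log(3),
               tolerance = 1e-9)
  big <- rnorm(2e5)
  expect_equal(differentialEntropy(big / sd(big)), 1.4189, tolerance = 1e-3)
  expect_error(differentialEntropy(rep(1, 10)), "zero variance")
})

test_that("AR band PSD is flat for white noise and peaks at tones", {
  set.seed(6)
  w <- rnorm(30 * 256)
  bands <- canonicalBands()
  for (b in seq_len(nrow(bands))) {
    p <- bandPsd(w, 256, bands$f_lo[b], min(bands$f_hi[b], 45))
    expect_lt(abs(p - 1 / 256) / (1 / 256), 0.2)
  }
  tone <- sin(2 * pi * 9 * seq(0, 10, by = 1 / 256)) + 0.01 * rnorm(2561)
  pa <- bandPsd(tone, 256, 8, 10)
  for (b in which(bands$name != "alpha_l")) {
    expect_gt(pa / bandPsd(tone, 256, bands$f_lo[b], min(bands$f_hi[b], 45)),
              10)
  }
  expect_error(bandPsd(rep(1, 1000), 256, 8, 10), "zero-variance")
})

test_that("the batch AR engine reproduces stats::ar.yw epoch by epoch", {
  set.seed(7)
  spe <- 256
  m <- matrix(rnorm(spe * 6), spe)
  r <- relaxEEG:::.epochFeaturesMatrix(m, 256, spe, 10, 12)
  grid <- seq(0, 128, length.out = 512)
  f <- grid[grid >= 10 & grid <= 12]
  for (j in 1:6) {
    fit <- stats::ar.yw(m[, j], aic = FALSE, order.max = 8)
    ref <- mean(relaxEEG:::.arSpectrum(fit$ar, fit$var.pred, 256, f))
    expect_equal(r$PSD[j], ref, tolerance = 1e-9)
  }
})

test_that("asymmetry features honor the conventional sign orientations", {
  eq <- list(E = c(alpha_l = 2, alpha_h = 3), DE = c(alpha_l = 1.5),
             ER = c(alpha_l__alpha_h = 0.8))
  out <- asymmetryFeatures(eq, eq)
  expect_equal(unname(out[c("ASM__alpha_l", "ERASM__alpha_l__alpha_h",
                            "DASM__alpha_l")]), c(0, 0, 0))
  expect_equal(unname(out["RASM__alpha_l"]), 1)
  out2 <- asymmetryFeatures(list(E = c(alpha_l = 1), DE = c(alpha_l = 2)),
                            list(E = c(alpha_l = 3), DE = c(alpha_l = 1)))
  expect_equal(unname(out2["ASM__alpha_l"]), 2)    # right - left
  expect_equal(unname(out2["DASM__alpha_l"]), 1)   # left - right
  expect_equal(unname(out2["RASM__alpha_l"]), 2)   # left / right
  expect_error(asymmetryFeatures(list(DE = c(alpha_l = 1)),
                                 list(DE = c(alpha_l = 0))), "division guard")
})

test_that("the feature dictionary enumerates exactly as specified", {
  keys <- featureKeySet()
  # independent combinatorial count
  expect_equal(nrow(keys), 4 * 7 * 3 + choose(7, 2) * 3)
  expect_equal(nrow(keys), 147)
  expect_false(anyDuplicated(keys$name) > 0)
  stats <- featureKeySet(set = "stats")
  expect_equal(nrow(stats), 147 + 2 + choose(7, 2) + 2 + 2)
  expect_true(all(stats$band[stats$family %in% c("ASM", "DASM", "RASM")]
                  %in% c("alpha_l", "alpha_h")))
  expect_equal(nrow(featureKeySet(set = "all")), 147 + 7 + 21 + 7 + 7)
  # pure function of inputs: stable order
  expect_identical(keys, featureKeySet())
  # ER pairs keep canonical ordering, lower band first
  er <- keys[keys$family == "ER", ]
  ord <- match(er$band, canonicalBands()$name) <
    match(er$band2, canonicalBands()$name)
  expect_true(all(ord))
})

test_that("feature tables assemble deterministically with labels attached", {
  ft <- signalFragmentTable()
  expect_s4_class(ft, "FeatureTable")
  expect_equal(nrow(ft), 147)
  expect_equal(ncol(ft), 5 * 3 * 29)
  expect_false(anyNA(featureMatrix(ft)))
  info <- fragmentInfo(ft)
  expect_true(all(table(info$segment_id) == 29))
  expect_true(all(info$r_state >= 1 & info$r_state <= 9))
  e <- signalCohort()
  ft2 <- suppressMessages(buildFeatureTable(e$recordings, e$labels,
                                            level = "fragment"))
  expect_identical(featureMatrix(ft), featureMatrix(ft2))
})

test_that("a wider fragment equals the mean of its per-second features", {
  e <- signalCohort()
  rec <- e$recordings[1]
  lab <- e$labels[1, ]
  one <- suppressMessages(buildFeatureTable(rec, lab, level = "fragment",
                                            modelLengthS = 6, windowS = 1,
                                            stepS = 1))
  two <- suppressMessages(buildFeatureTable(rec, lab, level = "fragment",
                                            modelLengthS = 6, windowS = 2,
                                            stepS = 2))
  m1 <- featureMatrix(one)
  m2 <- featureMatrix(two)
  expect_equal(m2[1, ], (m1[1, ] + m1[2, ]) / 2, tolerance = 1e-12)
  expect_equal(m2[3, ], (m1[5, ] + m1[6, ]) / 2, tolerance = 1e-12)
})

test_that("unusable and unlabeled segments are excluded with a message", {
  e <- signalCohort()
  lab <- e$labels
  lab$r_state[1] <- NA
  lab$usable[2] <- FALSE
  recs <- e$recordings
  recs[[2]]@usable <- FALSE
  expect_message(
    expect_message(
      ft <- buildFeatureTable(recs[1:4], lab[1:4, ], level = "fragment"),
      "unusable"),
    "without R-state")
  expect_equal(ncol(ft), 2 * 29)
})
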