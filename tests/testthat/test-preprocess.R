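# Front-end filtering, section extraction, band decomposition,
# fragmentation.

fsTest <- 256
tGrid <- seq(0, 10 - 1 / fsTest, by = 1 / fsTest)

test_that("front-end band-pass rejects stop-band and passes pass-band", {
  x60 <- sin(2 * pi * 60 * tGrid)
  x10 <- sin(2 * pi * 10 * tGrid)
  expect_lt(sd(bandpassFilter(x60, fsTest)) / sd(x60), 0.01)
  expect_lt(abs(sd(bandpassFilter(x10, fsTest)) / sd(x10) - 1), 0.05)
  dc <- bandpassFilter(rep(1, length(tGrid)), fsTest)
  expect_lt(sd(dc), 0.05)
  expect_lt(mean(abs(dc)), 0.05)
})

test_that("front-end filtering is zero-phase and idempotent in-band", {
  x10 <- sin(2 * pi * 10 * tGrid)
  y1 <- bandpassFilter(x10, fsTest)
  # zero phase: peak of cross-correlation with the input at zero lag
  cc <- stats::ccf(y1, x10, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  y2 <- bandpassFilter(y1, fsTest)
  expect_lt(sd(y2 - y1) / sd(y1), 0.02)
})

test_that("band-pass front-end validates its inputs", {
  expect_error(bandpassFilter(rnorm(1000), 80, 1, 45), "fs/2")
  expect_error(bandpassFilter(rnorm(10), 256), "too short")
  expect_error(bandpassFilter(rnorm(1000), 256, 45, 1), "invalid band")
})

test_that("sections are cut at the documented offsets", {
  fs <- 64  # counting samples directly
  n <- (120 + 156 + 120) * fs
  rec <- new("EegRecording", participantId = "P", sceneId = "S",
             segmentId = "P_s1", fs = fs,
             channels = c("FP1", "FPZ", "FP2"),
             samples = matrix(rep(seq_len(n), 3), ncol = 3),
             watchStart = 120 * fs, watchEnd = 276 * fs, usable = TRUE)
  ss <- extractSections(rec, 30)
  # rows are 1-based sample indices: pre covers [90, 120) s etc.
  expect_equal(sectionMatrix(ss, "pre")[1, 1], 90 * fs + 1)
  expect_equal(sectionMatrix(ss, "begin")[1, 1], 120 * fs + 1)
  expect_equal(sectionMatrix(ss, "end")[1, 1], 246 * fs + 1)
  expect_equal(sectionMatrix(ss, "post")[1, 1], 276 * fs + 1)
  expect_equal(nrow(sectionMatrix(ss, "pre")), 30 * fs)
  expect_equal(ss@overlapS, 0)

  # 60-s viewing: begin and end abut exactly
  rec60 <- new("EegRecording", participantId = "P", sceneId = "S",
               segmentId = "P_s2", fs = fs,
               channels = c("FP1", "FPZ", "FP2"),
               samples = matrix(0, (60 + 60 + 60) * fs, 3),
               watchStart = 60 * fs, watchEnd = 120 * fs, usable = TRUE)
  ss60 <- extractSections(rec60, 30)
  expect_equal(ss60@overlapS, 0)

  # 90-s viewing with 60-s sections: overlap 30 s, warned
  rec90 <- new("EegRecording", participantId = "P", sceneId = "S",
               segmentId = "P_s3", fs = fs,
               channels = c("FP1", "FPZ", "FP2"),
               samples = matrix(0, (90 + 90 + 90) * fs, 3),
               watchStart = 90 * fs, watchEnd = 180 * fs, usable = TRUE)
  expect_warning(ss90 <- extractSections(rec90, 60), "overlap")
  expect_equal(ss90@overlapS, 30)
  # rest shorter than the section
  expect_error(extractSections(rec90, 120), "insufficient")
})

test_that("band decomposition concentrates band-centered tones", {
  bands <- canonicalBands()
  for (b in seq_len(nrow(bands))) {
    fc <- (bands$f_lo[b] + min(bands$f_hi[b], 45)) / 2
    e <- vapply(decomposeBands(sin(2 * pi * fc * tGrid), fsTest),
                function(z) sum(z^2), 0)
    expect_gt(e[[b]] / sum(e), 0.9, label = bands$name[b])
  }
  # a tone on a shared band edge (10 Hz) splits between the two alpha bands
  e10 <- vapply(decomposeBands(sin(2 * pi * 10 * tGrid), fsTest),
                function(z) sum(z^2), 0)
  expect_gt((e10[["alpha_l"]] + e10[["alpha_h"]]) / sum(e10), 0.95)
})

test_that("band energies approximately account for broadband input energy", {
  # noise confined to the union of the bands: only skirt roll-off is lost
  u <- Reduce(`+`, lapply(seq_len(7), function(b) {
    bd <- canonicalBands()
    bandLimitedNoise(bd$f_lo[b], min(bd$f_hi[b], 45), 10, fsTest,
                     power = bd$f_hi[b] - bd$f_lo[b], seed = 80 + b)
  }))
  eu <- vapply(decomposeBands(u, fsTest), function(b) sum(b^2), 0)
  expect_lt(abs(sum(eu) - sum(u^2)) / sum(u^2), 0.15)
  # continuous 1-45 Hz noise additionally loses the 3-4, 7-8 and 30-31 Hz
  # inter-band gaps (~7% of the bandwidth)
  w <- bandLimitedNoise(1, 45, 10, fsTest, seed = 88)
  eb <- vapply(decomposeBands(w, fsTest), function(b) sum(b^2), 0)
  expect_lt(abs(sum(eb) - sum(w^2)) / sum(w^2), 0.20)

  z <- decomposeBands(rep(0, 2048), fsTest)
  expect_true(all(vapply(z, function(b) all(b == 0), TRUE)))
  expect_error(decomposeBands(tGrid, fsTest, bands = canonicalBands()[0, ]),
               "empty band")
})

test_that("fragment counts follow the closed-form enhancement formula", {
  expect_equal(fragmentCount(30, 2, 1), 29L)
  expect_equal(fragmentCount(60, 8, 4), 14L)
  expect_equal(fragmentCount(30, 30, 1), 1L)
  # property: every integer-divisible (L, W, step) triple
  set.seed(1)
  for (i in 1:25) {
    step <- sample(1:5, 1); k <- sample(1:20, 1); W <- sample(1:10, 1)
    L <- W + k * step
    x <- matrix(0, L * 8, 2)
    expect_length(fragmentSignal(x, 8, W, step), (L - W) / step + 1)
  }
  expect_warning(out <- fragmentSignal(matrix(0, 16, 1), 8, 10, 1), "longer")
  expect_length(out, 0)
})

test_that("fragments tile the signal with the right windows and labels", {
  x <- matrix(seq_len(30 * 8), ncol = 1)
  fr <- fragmentSignal(x, 8, 2, 1)
  expect_length(fr, 29)
  expect_equal(fr[[1]]$tStartS, 0)
  expect_equal(fr[[29]]$tStartS, 28)
  expect_equal(nrow(fr[[5]]$samples), 16)
  expect_equal(fr[[5]]$samples[1, 1], 4 * 8 + 1)  # window starts at 4 s
})
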