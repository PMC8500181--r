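# Paired contrasts, selection, consistency.

test_that("contrast specs cover exactly the three supported comparisons", {
  cs <- contrastSpec("pre_end")
  expect_equal(cs$a, "pre")
  expect_equal(cs$b, "end")
  expect_error(contrastSpec("begin_post"))
})

test_that("paired tests match the closed-form t on hand-built deltas", {
  # three segments, two participants; feature f1 has deltas (1, 2, 3)
  vals <- matrix(c(0, 0, 0, 1, 2, 3,    # f1: pre then end
                   5, 5, 5, 5, 5, 5),   # f2: identical sections
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("f1", "f2"), NULL))
  tab <- manualSectionTable(
    vals, segments = rep(c("s1", "s2", "s3"), 2),
    sections = rep(c("pre", "end"), each = 3),
    participants = rep(c("pA", "pA", "pB"), 2))
  res <- pairedContrast(tab, "pre_end")
  r1 <- res[res$feature == "f1", ]
  expect_equal(r1$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r1$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(r1$mean_delta, 2)
  expect_equal(r1$direction, "increase")
  expect_equal(r1$n_pairs, 3)
  # identical sections: degenerate convention
  r2 <- res[res$feature == "f2", ]
  expect_equal(r2$t_statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$direction, "none")
  expect_true(r2$degenerate)
})

test_that("flipping the section order negates t and keeps p", {
  set.seed(11)
  vals <- matrix(rnorm(3 * 12), nrow = 3,
                 dimnames = list(paste0("f", 1:3), NULL))
  segs <- rep(sprintf("s%d", 1:6), 2)
  secs <- rep(c("begin", "end"), each = 6)
  parts <- rep(rep(c("pA", "pB", "pC"), each = 2), 2)
  tab <- manualSectionTable(vals, segs, secs, parts)
  fwd <- pairedContrast(tab, "begin_end")
  vals2 <- vals[, c(7:12, 1:6)]
  tab2 <- manualSectionTable(vals2, segs, secs, parts)
  rev <- pairedContrast(tab2, "begin_end")
  expect_equal(rev$t_statistic, -fwd$t_statistic, tolerance = 1e-12)
  expect_equal(rev$mean_delta, -fwd$mean_delta, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("significance selection thresholds and adjusts correctly", {
  res <- data.frame(feature = c("a", "b", "c"),
                    p_value = c(0.01, 0.04, 0.2),
                    stringsAsFactors = FALSE)
  keep <- selectSignificant(res, 0.05)
  expect_equal(keep$feature, c("a", "b"))
  bh <- selectSignificant(res, 0.05, correction = "benjamini_hochberg")
  expect_equal(bh$feature, "a")   # 0.01*3 = 0.03 < 0.05; 0.04*3/2 = 0.06 out
  none <- data.frame(feature = "x", p_value = 0.5)
  expect_equal(nrow(selectSignificant(none, 0.05)), 0)
  expect_equal(nrow(selectSignificant(res, 1 - 1e-9)), 3)
  expect_equal(nrow(selectSignificant(res, 1e-9)), 0)
  expect_error(selectSignificant(res, 1.2), "alpha")
  expect_error(selectSignificant(res[0, ], 0.05), "non-empty")
})

test_that("consistency requires a shared strict sign across participants", {
  expect_equal(consistencyTrend(rep(0.3, 5)),
               list(direction = "increase", consistent = TRUE))
  expect_equal(consistencyTrend(c(1, -1)),
               list(direction = "none", consistent = FALSE))
  d <- c(rep(1, 25), -1)
  expect_equal(consistencyTrend(d),
               list(direction = "increase", consistent = FALSE))
  expect_equal(consistencyTrend(d, toleranceFrac = 0.05),
               list(direction = "increase", consistent = TRUE))
  # zero deltas count against consistency
  expect_false(consistencyTrend(c(1, 1, 0))$consistent)
  expect_error(consistencyTrend(1), "participants")
})

test_that("an injected alpha slope is flagged for the pre-end contrast", {
  e <- signalCohort()
  st <- cachedTable("signalStats", function() {
    suppressMessages(buildFeatureTable(e$recordings, e$labels,
                                       level = "section",
                                       featureSet = "stats",
                                       sections = c("pre", "end")))
  })
  res <- pairedContrast(st, "pre_end")
  hit <- res[grepl("^E__alpha_h__", res$feature), ]
  expect_true(all(hit$p_value < 0.05))
  expect_true(all(hit$direction == "increase"))
  expect_true(all(hit$consistent))
  down <- res[grepl("^E__beta_h__", res$feature), ]
  expect_true(all(down$p_value < 0.05 & down$direction == "decrease"))
  sel <- selectSignificant(res)
  expect_true(all(diff(sel$p_value) >= 0))
  expect_true(all(c(hit$feature, down$feature) %in% sel$feature))
})
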