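test_that("relaxivity lines are fit exactly and errors propagate", {
  conc <- c(0.5, 1, 2, 4)
  rf <- fit_relaxivity(conc, 0.3 + 2.0 * conc)
  expect_equal(rf$slope, 2.0, tolerance = 1e-12)
  expect_equal(rf$intercept, 0.3, tolerance = 1e-12)
  expect_equal(rf$rmsd, 0, tolerance = 1e-12)
  # two points: exact interpolation, no residual-based slope error
  rf2 <- fit_relaxivity(c(1, 2), c(2.3, 4.3))
  expect_equal(rf2$slope, 2.0)
  expect_equal(rf2$rmsd, 0, tolerance = 1e-12)
  expect_true(is.na(rf2$slope_se))
  expect_error(fit_relaxivity(c(1, 1, 1), c(1, 2, 3)), "unidentifiable")
  expect_error(fit_relaxivity(1, 1), "at least 2")
  # propagated slope error from per-point measurement errors
  rf3 <- fit_relaxivity(c(0, 1, 2, 3), c(0, 1, 2, 3), se = rep(0.1, 4))
  sxx <- sum((0:3 - 1.5)^2)
  expect_equal(rf3$slope_se_prop,
               sqrt(sum(((0:3 - 1.5) / sxx)^2 * 0.1^2)))
})

test_that("simulated adjuvant series recover the class relaxivity", {
  # AH concentration series at SNR 100 across many seeds: the mean fitted
  # slope lands within 1 % of the generating relaxivity 0.93
  p <- lab_profile("L", tau = 1000e-6, n_echoes = 600, n_scans = 16,
                   noise_sd = 0.01)
  m <- relaxation_model(r2_0 = 0.35, relaxivity = 0.93)
  conc <- c(0.31, 0.63, 1.25, 2.5, 5.0, 10.0)
  slopes <- numeric(100)
  for (s in 1:100) {
    al <- vapply(seq_along(conc), function(i) {
      fit_monoexponential(
        simulate_decay(m, conc[i], FALSE, p, seed = 700 * s + i))$alpha
    }, 0)
    slopes[s] <- fit_relaxivity(conc, al)$slope
  }
  expect_lt(abs(mean(slopes) - 0.93) / 0.93, 0.01)
})

test_that("span and CV follow their definitions", {
  expect_equal(slope_span(c(1, 3)), 2)
  expect_equal(slope_span(5), 0)
  expect_error(slope_span(numeric(0)), "empty")
  expect_equal(relaxivity_cv(c(1, 1, 1)), 0)
  expect_equal(relaxivity_cv(c(1, 3)), 100 * sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cv_from_stats(2, 0.5), 25)
  expect_error(cv_from_stats(0, 1), "undefined")
  # population-sd convention available by flag
  expect_equal(relaxivity_cv(c(1, 3), population = TRUE), 50)
  st <- slope_stats(c(1, 3))
  expect_equal(st[["mu"]], 2)
  expect_equal(st[["sigma"]], sqrt(2))
  # CV is scale invariant; span scales linearly
  x <- c(0.71, 0.85, 0.93, 1.08)
  expect_equal(relaxivity_cv(7.7 * x), relaxivity_cv(x))
  expect_equal(slope_span(7.7 * x), 7.7 * slope_span(x))
})

test_that("freeze/thaw percent change follows the ratio definition", {
  expect_equal(freeze_thaw_change(2.8, 2.8), 0)
  expect_equal(freeze_thaw_change(0.9, 1.0), 10)
  expect_equal(freeze_thaw_change(0.5, 1.0), 50)
  expect_error(freeze_thaw_change(1, 0), "> 0")
  # ratio r and 1/r give opposite-signed changes
  r <- 0.8
  expect_equal(sign(freeze_thaw_change(r, 1)),
               -sign(freeze_thaw_change(1, r)))
  expect_equal(freeze_thaw_change(r, 1), (1 - r) * 100)
  expect_equal(freeze_thaw_change(1, r), (1 - 1 / r) * 100)
})

test_that("outlier assessment flags by threshold, band and direction", {
  conc <- c(0.31, 0.63, 1.25, 2.5, 5)
  calib <- fit_relaxivity(conc, 0.35 + 1.98 * conc, lab_id = "Lab1",
                          sample_class = "AP")
  r2_u <- 0.35 + 1.98 * 1.25
  # identical pair: no change, not flagged
  oa0 <- assess_outlier(r2_u, r2_u, calib)
  expect_equal(oa0$percent_change, 0)
  expect_false(oa0$flagged)
  expect_equal(oa0$direction, "none")
  # 15 % drop: flagged as a decrease
  oa <- assess_outlier(0.85 * r2_u, r2_u, calib)
  expect_true(oa$flagged)
  expect_equal(oa$direction, "decrease")
  expect_equal(oa$percent_change, 15)
  expect_equal(oa$ratio, 0.85)
  # percent_change = (1 - ratio) * 100 exactly
  expect_equal(oa$percent_change, (1 - oa$ratio) * 100)
  # an anomalous increase (e.g. unmixed unfrozen mate) flags the other way
  oa_up <- assess_outlier(1.2 * r2_u, r2_u, calib)
  expect_true(oa_up$flagged)
  expect_equal(oa_up$direction, "increase")
  # sub-threshold changes inside the band are not flagged
  expect_false(assess_outlier(0.95 * r2_u, r2_u, calib)$flagged)
  # lab/class mismatches are integrity errors
  expect_error(assess_outlier(1, 2, calib, lab_id = "Lab9"), "mismatch")
  expect_error(assess_outlier(1, 2, calib, sample_class = "AH"), "mismatch")
})

test_that("zero-slope verdicts separate controls from adjuvants", {
  conc <- c(1, 2, 3, 4, 5)
  # exact zero-slope data
  rf0 <- fit_relaxivity(conc, rep(0.35, 5), se = rep(0.01, 5))
  expect_equal(zero_slope_test(rf0), "consistent_with_zero")
  # a strong true slope
  rf1 <- fit_relaxivity(conc, 0.35 + 1.98 * conc, se = rep(0.01, 5))
  expect_equal(zero_slope_test(rf1), "nonzero")
  # no usable slope error: indeterminate
  rf2 <- fit_relaxivity(c(1, 2), c(1, 1.01))
  expect_equal(zero_slope_test(rf2), "indeterminate")
})

test_that("study reports aggregate fits, dispersion, outliers and controls", {
  man <- default_manifest()
  profs <- default_lab_profiles(artifacts = FALSE)
  traces <- simulate_study(default_class_models(), man, profs, seed = 5)
  fits <- lapply(traces, fit_monoexponential)
  tab <- data.frame(
    lab_id = vapply(traces, function(x) x$meta$lab_id, ""),
    sample_code = vapply(traces, function(x) x$meta$sample_code, ""),
    alpha = vapply(fits, function(f) f$alpha, 0),
    alpha_se = vapply(fits, function(f) f$param_se[["alpha"]], 0),
    row.names = NULL)
  rep <- build_report(tab, man)
  # 7 labs x 4 concentration-series classes
  expect_equal(nrow(rep$relaxivity_table), 28L)
  expect_equal(sort(unique(rep$relaxivity_table$sample_class)),
               c("AH", "AP", "ETFE", "mAb"))
  expect_equal(nrow(rep$dispersion), 4L)
  # stressed AH + AP pair per lab
  expect_equal(nrow(rep$outliers), 14L)
  expect_true(all(rep$outliers$flagged))
  expect_true(all(rep$outliers$direction == "decrease"))
  # adjuvant relaxivities rank AP > AH > mAb in every lab
  rt <- rep$relaxivity_table
  for (lab in unique(rt$lab_id)) {
    s <- function(cls) rt$slope[rt$lab_id == lab & rt$sample_class == cls]
    expect_true(s("AP") > s("AH"))
    expect_true(s("AH") > s("mAb"))
  }
  # ETFE negative control reads as zero slope for most labs
  ctrl <- rep$control_tests
  etfe <- ctrl$outcome[ctrl$sample_class == "ETFE"]
  expect_gte(sum(etfe == "consistent_with_zero"), 6L)
  adj <- ctrl$outcome[ctrl$sample_class %in% c("AH", "AP")]
  expect_true(all(adj == "nonzero"))
})

test_that("empty input and duplicate submissions are handled", {
  man <- default_manifest()
  rep0 <- build_report(NULL, man, provenance = list(seed = 1))
  expect_null(rep0$relaxivity_table)
  expect_equal(rep0$provenance$seed, 1)
  # a duplicated (lab, sample) row: later measurement wins, anomaly logged
  tab <- data.frame(
    lab_id = "Lab1",
    sample_code = c("AH1", "AH2", "AH3", "AH4", "AH1"),
    alpha = c(99, 0.35 + 0.93 * 0.63, 0.35 + 0.93 * 1.25,
              0.35 + 0.93 * 2.5, 0.35 + 0.93 * 0.31),
    alpha_se = 0.01)
  rep <- build_report(tab, man)
  expect_match(rep$anomalies, "duplicate", all = FALSE)
  expect_equal(rep$relaxivity_table$slope[1], 0.93, tolerance = 1e-9)
  # unknown codes are integrity errors
  tab$sample_code[2] <- "GHOST"
  expect_error(build_report(tab, man), "not in manifest")
})
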