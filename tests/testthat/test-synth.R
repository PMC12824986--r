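test_that("true rates follow the linear concentration law", {
  # concentration-independent negative control
  etfe <- relaxation_model(r2_0 = 0.35, relaxivity = 0)
  expect_equal(true_r2(etfe, 0), 0.35)
  expect_equal(true_r2(etfe, 1e5), 0.35)
  # linear response and freeze/thaw reduction
  m <- relaxation_model(r2_0 = 0.3, relaxivity = 2.0,
                        freeze_thaw_delta = 0.15)
  expect_equal(true_r2(m, 1.25), 2.8)
  expect_equal(true_r2(m, 1.25, stressed = TRUE), 2.8 * 0.85)
  expect_error(true_r2(m, -1), "concentration")
  expect_error(relaxation_model(r2_0 = -1), "r2_0")
  expect_error(relaxation_model(freeze_thaw_delta = 1), "freeze_thaw_delta")
})

test_that("echo grids reflect the CPMG timing", {
  p <- lab_profile("L", tau = 500e-6, n_echoes = 3)
  expect_equal(echo_grid(p), c(0.001, 0.002, 0.003))
  pf <- lab_profile("L", tau = 500e-6, n_echoes = 1000,
                    mode = "frequency_domain")
  g <- echo_grid(pf)
  expect_length(g, 17L)
  expect_true(all(diff(g) > 0))
  expect_equal(range(g), c(0.001, 1))
  expect_error(lab_profile("L", tau = 0), "tau")
  expect_error(lab_profile("L", tau = 1e-2), "faithful")
  expect_error(lab_profile("L", n_scans = 2), "faithful")
  # the faithful guard can be lifted explicitly
  expect_s3_class(lab_profile("L", tau = 1e-2, faithful = FALSE),
                  "lab_profile")
})

test_that("noiseless artifact-free simulation round-trips the fitter", {
  m <- relaxation_model(r2_0 = 0.3, relaxivity = 2.0)
  p <- lab_profile("L", tau = 500e-6, n_echoes = 1000, noise_sd = 0)
  tr <- simulate_decay(m, 1.25, FALSE, p, amplitude = 2, offset = 0.1,
                       seed = 1)
  f <- fit_monoexponential(tr)
  expect_lt(abs(f$alpha - 2.8) / 2.8, 1e-9)
  expect_lt(abs(f$A - 2) / 2, 1e-9)
  expect_lt(abs(f$b - 0.1) / 0.1, 1e-9)
  # a clean phase rotation is recovered exactly
  pr <- lab_profile("L", tau = 500e-6, n_echoes = 1000, noise_sd = 0,
                    phase_offset = pi / 6)
  trp <- simulate_decay(m, 1.25, FALSE, pr, seed = 1)
  expect_lt(abs(as.numeric(estimate_phase(trp)) - pi / 6), 1e-6)
})

test_that("study simulation is deterministic and complete", {
  man <- default_manifest()
  profs <- default_lab_profiles()
  expect_length(profs, 7L)
  s1 <- simulate_study(default_class_models(), man, profs, seed = 11)
  expect_length(s1, 7L * 24L)
  s2 <- simulate_study(default_class_models(), man, profs, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_study(default_class_models(), man, profs, seed = 12)
  expect_false(identical(s1[[1]]$signal, s3[[1]]$signal))
  # missing class model is a configuration error
  expect_error(
    simulate_study(list(AH = relaxation_model(relaxivity = 1)), man, profs,
                   seed = 1),
    "no relaxation model")
  expect_error(simulate_decay(default_class_models()$AH, 1, FALSE,
                              profs[[1]]),
               "seed")
})

test_that("AC-line oscillation perturbs the fit no more than equal-power noise", {
  # constant-amplitude oscillations centred at zero are expected to act on
  # the exponential fit like thermal noise of the same RMS power
  tt <- seq(0.001, 0.5, by = 0.001)
  clean <- exp(-2.8 * tt) + 0.02
  a_ac <- 0.01
  sd_eq <- a_ac / sqrt(2)           # equal RMS power
  err_ac <- err_noise <- numeric(100)
  for (s in 1:100) {
    withr::with_seed(s, {
      f_ac <- stats::runif(1, 45, 65)
      ph <- stats::runif(1, 0, 2 * pi)
      y_ac <- clean + a_ac * sin(2 * pi * f_ac * tt + ph)
      y_no <- clean + stats::rnorm(length(tt), 0, sd_eq)
    })
    err_ac[s] <- fit_monoexponential(make_trace(tt, y_ac))$alpha - 2.8
    err_noise[s] <- fit_monoexponential(make_trace(tt, y_no))$alpha - 2.8
  }
  expect_lt(sqrt(mean(err_ac^2)), sqrt(mean(err_noise^2)))
})

test_that("simulated ETFE series are statistically flat in every lab", {
  profs <- default_lab_profiles(artifacts = FALSE)
  m <- relaxation_model(r2_0 = 0.35, relaxivity = 0)
  conc <- c(6250, 12500, 25000, 50000, 100000)
  covered <- logical(length(profs))
  for (p in seq_along(profs)) {
    al <- se <- numeric(length(conc))
    for (i in seq_along(conc)) {
      tr <- simulate_decay(m, conc[i], FALSE, profs[[p]],
                           seed = 500 * p + i)
      f <- fit_monoexponential(tr)
      al[i] <- f$alpha
      se[i] <- f$param_se[["alpha"]]
    }
    rf <- fit_relaxivity(conc, al, se = se)
    covered[p] <- abs(rf$slope) <= 2 * rf$slope_se_prop
  }
  # each lab's 95 % slope interval should cover zero; allow the expected
  # occasional single miss at this coverage level
  expect_gte(sum(covered), length(profs) - 1L)
})

test_that("a settled lab yields an outlier adjuvant slope", {
  # emulates a lab that missed the resuspension instructions: adjuvant
  # relaxivity is scaled down before simulation and its fitted slope
  # separates cleanly from the compliant labs
  man <- default_manifest()
  ah <- man[man$sample_class == "AH" & !man$stressed, ]
  models <- default_class_models()
  profs <- default_lab_profiles(artifacts = FALSE)[1:3]
  profs[[3]]$settled <- TRUE
  traces <- simulate_study(models, ah, profs, seed = 21)
  slopes <- vapply(seq_along(profs), function(p) {
    al <- vapply(seq_len(nrow(ah)), function(e) {
      fit_monoexponential(traces[[(p - 1) * nrow(ah) + e]])$alpha
    }, 0)
    fit_relaxivity(ah$concentration, al)$slope
  }, 0)
  expect_lt(slopes[3], 0.8 * min(slopes[1:2]))
  expect_equal(slopes[3] / mean(slopes[1:2]), 0.6, tolerance = 0.05)
})
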