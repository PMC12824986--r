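mod28 <- relaxation_model(r2_0 = 0.3, relaxivity = 2.0)

test_that("zero-order phase estimation matches construction and oracle", {
  # purely real positive decay: phase not applicable, reported as 0
  tr_real <- make_decay()
  phi0 <- estimate_phase(tr_real)
  expect_equal(as.numeric(phi0), 0)
  expect_true(attr(phi0, "real_only"))
  # clean rotation recovered to numerical precision
  z <- tr_real$signal * exp(1i * pi / 6)
  tr_rot <- decay_trace(tr_real$time, z, is_quadrature = TRUE)
  expect_lt(abs(estimate_phase(tr_rot) - pi / 6), 1e-9)
  # noisy rotation agrees with the grid-search minimizer of imaginary power
  p <- lab_profile("L", tau = 500e-6, n_echoes = 500, n_scans = 8,
                   noise_sd = 0.01, phase_offset = 0.1)
  tr_noisy <- simulate_decay(mod28, 1.25, FALSE, p, seed = 7)
  expect_lt(abs(as.numeric(estimate_phase(tr_noisy)) -
                  oracle_grid_phase(tr_noisy)), 1e-4)
})

test_that("phase application is an exact involution", {
  p <- lab_profile("L", tau = 500e-6, n_echoes = 300, n_scans = 8,
                   noise_sd = 0.01, phase_offset = 0.3)
  tr <- simulate_decay(mod28, 1.25, FALSE, p, seed = 2)
  expect_identical(apply_phase(tr, 0)$signal, tr$signal)
  back <- apply_phase(apply_phase(tr, 0.3), -0.3)
  expect_equal(back$signal, tr$signal, tolerance = 1e-14)
  # correcting the estimated phase pushes the signal into the real channel
  corr <- apply_phase(tr, estimate_phase(tr))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(Im(corr$signal)), 0.01 * rms(Re(corr$signal)))
})

test_that("eddy-current model fitting recovers exact and noisy transients", {
  tt <- seq(2e-5, 0.01, by = 2e-5)
  truth <- eddy_current_model(amplitude = 0.05, decay_rate = 1000,
                              frequency = 5000, phase = 0)
  y <- eval_eddy(truth, tt)
  em <- fit_eddy_current(make_trace(tt, y))
  expect_lt(abs(em$amplitude - 0.05) / 0.05, 1e-6)
  expect_lt(abs(em$decay_rate - 1000) / 1000, 1e-6)
  expect_lt(abs(em$frequency - 5000) / 5000, 1e-6)

  # flat residual: near-zero amplitude, flagged degenerate
  em0 <- fit_eddy_current(make_trace(tt, numeric(length(tt))))
  expect_lt(em0$amplitude, 1e-12)
  expect_true(attr(em0, "flagged"))

  # noisy transient: frequency recovered within one FFT bin of the window
  y_noisy <- y + withr::with_seed(3, stats::rnorm(length(tt), 0, 0.05 / 20))
  em_n <- fit_eddy_current(make_trace(tt, y_noisy))
  n_win <- length(attr(em_n, "window_idx"))
  bin <- 1 / (n_win * 2e-5)
  expect_lt(abs(em_n$frequency - 5000), bin)

  # too few points in the early-time window
  expect_error(fit_eddy_current(make_trace(c(1, 2, 3, 4, 5, 6), 1:6)),
               "insufficient")
})

test_that("eddy subtraction round-trips and never inflates the residual", {
  m <- eddy_current_model(amplitude = 0.02, decay_rate = 300,
                          frequency = 180, phase = 0.4)
  p <- lab_profile("L", tau = 500e-6, n_echoes = 1000, n_scans = 16,
                   noise_sd = 0.01, eddy = m)
  zero <- eddy_current_model(0, 1, 0, 0)
  for (s in c(5, 6, 7)) {
    tr <- simulate_decay(mod28, 1.25, FALSE, p, seed = s)
    expect_identical(subtract_eddy(tr, zero)$signal, tr$signal)
    # subtract then re-add: identity
    readd <- subtract_eddy(tr, m)
    readd$signal <- readd$signal + complex(real = eval_eddy(m, tr$time))
    expect_equal(readd$signal, tr$signal, tolerance = 1e-14)
    # the correction pipeline must not worsen the exponential fit
    rms_before <- fit_monoexponential(tr)$residual_rms
    ct <- correct_trace(tr, phase = FALSE, ac = FALSE)
    expect_lte(ct$fit$residual_rms, rms_before + 1e-12)
    expect_gt(ct$report$r2_shift_eddy, 0)
  }
})

test_that("AC spike detection finds tones and rejects white noise", {
  tt <- seq(0.001, 0.5, by = 0.001)          # 500 points, df = 2 Hz
  # white noise alone: no spikes at the default threshold
  y_noise <- withr::with_seed(11, stats::rnorm(length(tt), 0, 0.01))
  expect_equal(nrow(detect_ac_artifacts(make_trace(tt, y_noise))), 0L)
  # white-noise false-positive rate across many seeds stays below 5 %
  fp <- 0L
  for (s in 1:100) {
    y <- withr::with_seed(s, stats::rnorm(length(tt), 0, 0.01))
    if (nrow(detect_ac_artifacts(make_trace(tt, y))) > 0) fp <- fp + 1L
  }
  expect_lt(fp / 100, 0.05)

  # a 60 Hz tone at 10x the noise sd: one spike in the right bin
  y60 <- y_noise + 0.1 * sin(2 * pi * 60 * tt)
  sp <- detect_ac_artifacts(make_trace(tt, y60))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$frequency[1], 60, tolerance = 1e-9)

  # two tones, reported strongest first, magnitudes matching the DFT
  y2 <- y_noise + 0.05 * sin(2 * pi * 50 * tt) + 0.08 * sin(2 * pi * 150 * tt)
  sp2 <- detect_ac_artifacts(make_trace(tt, y2))
  expect_equal(sp2$frequency[1:2], c(150, 50), tolerance = 1e-9)
  # DFT magnitude oracle for an on-bin tone: n * amplitude / 2
  n <- length(tt)
  dft_mag <- function(y, f) Mod(sum(y * exp(-2i * pi * f * tt)))
  expect_equal(sp2$magnitude[1], dft_mag(y2, 150), tolerance = 1e-9)
  expect_equal(sp2$magnitude[1], n * 0.08 / 2, tolerance = 0.05)

  # non-uniform grids are refused explicitly
  tt_bad <- c(tt[1:100], tt[101:500] + 2e-4)
  expect_error(detect_ac_artifacts(make_trace(tt_bad, y_noise)),
               "non-uniform")
})

test_that("noise estimation is robust", {
  tt <- seq(0.001, 1, by = 0.001)
  expect_equal(estimate_noise(make_trace(tt, numeric(1000))), 0)
  y <- withr::with_seed(5, stats::rnorm(1000, 0, 0.01))
  est <- estimate_noise(make_trace(tt, y))
  expect_lt(abs(est - 0.01) / 0.01, 0.10)
  # one gross outlier barely moves the estimate
  y_out <- y
  y_out[500] <- 5
  est_out <- estimate_noise(make_trace(tt, y_out))
  expect_lt(abs(est_out - est) / est, 0.05)
  # quadrature residuals pool both channels
  z <- withr::with_seed(6, complex(real = stats::rnorm(1000, 0, 0.01),
                                   imaginary = stats::rnorm(1000, 0, 0.01)))
  estq <- estimate_noise(decay_trace(tt, z, is_quadrature = TRUE))
  expect_lt(abs(estq - 0.01) / 0.01, 0.10)
})

test_that("the correction pipeline is idempotent", {
  p <- lab_profile("L", tau = 500e-6, n_echoes = 2000, n_scans = 16,
                   noise_sd = 0.01,
                   eddy = eddy_current_model(0.02, 300, 180, 0.4),
                   phase_offset = 0.03, ac_amplitude = 0.004, ac_freq = 60)
  tr <- simulate_decay(mod28, 1.25, FALSE, p, seed = 7)
  ct1 <- correct_trace(tr)
  ct2 <- correct_trace(ct1$trace)
  expect_lt(correction_impact(ct1$fit, ct2$fit), 0.01)
})
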