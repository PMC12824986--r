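#' Estimate the zero-order quadrature phase of a decay
#'
#' Small phase distortions accumulated over many 180-degree pulses rotate
#' echo signal from the real into the imaginary channel.  The zero-order
#' phase is estimated in closed form as
#' `phi = atan2(sum(Im * w), sum(Re * w))` with weights `w = |signal|`,
#' restricted to the high-SNR window (the first half of the points by
#' default); this is the rotation that minimizes the weighted imaginary
#' power of `signal * exp(-i * phi)`.
#'
#' @param trace A [decay_trace()] with at least 3 points.
#' @param window_frac Fraction of the (earliest) points used (default 0.5).
#' @return Phase in radians, in (-pi, pi\].  For a real-only trace, `0`
#'   with attribute `real_only = TRUE` (phase is not applicable).
#' @export
estimate_phase <- function(trace, window_frac = 0.5) {
  stopifnot(inherits(trace, "decay_trace"))
  if (!trace$is_quadrature) {
    return(structure(0, real_only = TRUE))
  }
  n <- length(trace$time)
  idx <- seq_len(max(3L, ceiling(window_frac * n)))
  z <- trace$signal[idx]
  w <- Mod(z)
  atan2(sum(Im(z) * w), sum(Re(z) * w))
}

#' Apply a zero-order phase correction
#'
#' Multiplies the complex signal by `exp(-i * phi)`, rotating the echo
#' signal back into the real channel.  Applying `phi` then `-phi` is the
#' identity.  The cumulative applied phase is tracked in the
#' `"phase_applied"` attribute.
#'
#' @param trace A [decay_trace()].
#' @param phi Phase in radians.
#' @return The rotated [decay_trace()].
#' @export
apply_phase <- function(trace, phi) {
  stopifnot(inherits(trace, "decay_trace"))
  z <- trace$signal * exp(-1i * phi)
  out <- decay_trace(trace$time, z,
                     is_quadrature = trace$is_quadrature || phi != 0,
                     meta = trace$meta)
  prev <- attr(trace, "phase_applied")
  attr(out, "phase_applied") <- (if (is.null(prev)) 0 else prev) + phi
  out
}

# residual trace helper: real-channel residual of a fit, as a decay_trace
# (imaginary channel carried through unchanged)
residual_trace <- function(trace, fit) {
  stopifnot(inherits(trace, "decay_trace"), inherits(fit, "fit_result"))
  res <- Re(trace$signal) - predict_decay(fit, trace$time)
  decay_trace(trace$time, complex(real = res, imaginary = Im(trace$signal)),
              is_quadrature = trace$is_quadrature, meta = trace$meta)
}

# default eddy-fit window: first 10% of points or t < 5 ms, whichever is
# larger (the eddy transient is sub-millisecond, much faster than water)
.eddy_window_idx <- function(time, window = NULL) {
  if (is.null(window)) {
    n10 <- ceiling(0.1 * length(time))
    t_end <- max(5e-3, time[n10])
  } else {
    t_end <- window
  }
  which(time <= t_end)
}

#' Fit an exponentially damped sinusoid to an early-time residual
#'
#' Models the eddy-current transient
#' `amplitude * exp(-decay_rate * t) * sin(2*pi*frequency*t + phase)` on
#' the early-time window of a fit residual, by Levenberg-Marquardt least
#' squares with multi-start over the frequency: candidate frequencies come
#' from the dominant FFT bin of the window residual plus/minus 2 bins
#' (uniform grids), or a log-spaced frequency sweep (non-uniform grids).
#'
#' @param residual A [decay_trace()] holding the residual (trace minus the
#'   current mono-exponential model) in its real channel.
#' @param window End of the fit window in seconds; default is the larger of
#'   the first 10 % of points and t < 5 ms.
#' @return An [eddy_current_model()] with attributes `ssr` (residual sum of
#'   squares on the window), `flagged` (`TRUE` for a degenerate/flat
#'   residual) and `window_idx`.
#' @export
fit_eddy_current <- function(residual, window = NULL) {
  stopifnot(inherits(residual, "decay_trace"))
  idx <- .eddy_window_idx(residual$time, window)
  if (length(idx) < 6L) {
    stop("fit_eddy_current: insufficient data, eddy window has ",
         length(idx), " points (need >= 6)")
  }
  tt <- residual$time[idx]
  y <- Re(residual$signal)[idx]
  scale_y <- max(abs(y))
  if (scale_y < 1e-12) {
    out <- eddy_current_model(0, 1, 0, 0)
    attr(out, "ssr") <- 0
    attr(out, "flagged") <- TRUE
    attr(out, "window_idx") <- idx
    return(out)
  }
  # candidate frequencies from the dominant FFT bins (+/- 2) of the window
  # residual, plus the dominant bins of an early sub-window where a fast
  # transient stands out against slower oscillations
  dt <- diff(tt)
  uniform <- max(abs(dt - mean(dt))) < 1e-9 * mean(dt)
  fft_peaks <- function(v, dtm) {
    sp <- Mod(stats::fft(v))
    half <- 2:(floor(length(v) / 2) + 1)
    k_peak <- half[which.max(sp[half])] - 1L
    df <- 1 / (length(v) * dtm)
    pmax((k_peak + (-2:2)) * df, df / 2)
  }
  if (uniform && length(tt) >= 8L) {
    f_cand <- fft_peaks(y, mean(dt))
    n_sub <- max(8L, ceiling(0.05 * length(y)))
    if (n_sub < length(y)) {
      f_cand <- c(f_cand, fft_peaks(y[seq_len(n_sub)], mean(dt)))
    }
  } else {
    f_lo <- 1 / (max(tt) - min(tt))
    f_hi <- 0.5 / min(dt)
    f_cand <- exp(seq(log(f_lo), log(f_hi), length.out = 8))
  }
  span <- max(tt) - min(tt)
  model_fn <- function(p) {
    p[1] * exp(-exp(p[2]) * tt) * sin(2 * pi * p[3] * tt + p[4])
  }
  # a genuine eddy transient dies off within the fit window; solutions
  # whose damping is slower than ~2/span describe a persistent
  # oscillation (e.g. AC-line pickup), not an eddy current
  min_rate <- 2 / span
  best <- NULL
  best_ssr <- Inf
  best_any <- NULL
  best_any_ssr <- Inf
  for (f0 in unique(f_cand)) {
    for (r0 in c(3 / span, 30 / span)) {
      for (ph0 in c(0, pi / 2)) {
        start <- c(a = scale_y, lrate = log(r0), f = f0, ph = ph0)
        fit <- tryCatch(
          suppressWarnings(minpack.lm::nls.lm(
            par = start, fn = function(p) y - model_fn(p),
            control = minpack.lm::nls.lm.control(maxiter = 100))),
          error = function(e) NULL)
        if (is.null(fit)) next
        if (fit$deviance < best_any_ssr) {
          best_any <- fit
          best_any_ssr <- fit$deviance
        }
        if (exp(fit$par[["lrate"]]) >= min_rate && fit$deviance < best_ssr) {
          best <- fit
          best_ssr <- fit$deviance
        }
      }
    }
  }
  no_transient <- is.null(best)
  if (no_transient) {
    best <- best_any
    best_ssr <- best_any_ssr
  }
  p <- best$par
  amp <- p[["a"]]
  freq <- p[["f"]]
  phase <- p[["ph"]]
  if (freq < 0) {         # sin(-wt + ph) == sin(wt + (pi - ph))
    freq <- -freq
    phase <- pi - phase
  }
  if (amp < 0) {          # fold a negative amplitude into the phase
    amp <- -amp
    phase <- phase + pi
  }
  phase <- atan2(sin(phase), cos(phase))
  out <- eddy_current_model(amplitude = amp, decay_rate = exp(p[["lrate"]]),
                            frequency = freq, phase = phase)
  attr(out, "ssr") <- best_ssr
  attr(out, "flagged") <- no_transient
  attr(out, "window_idx") <- idx
  out
}

#' Subtract a fitted eddy-current model from a trace
#'
#' Evaluates the damped sinusoid on the trace's grid and subtracts it from
#' the real channel (the eddy transient lives in the detected echo
#' intensity); the imaginary channel is untouched.  Subtracting then
#' re-adding the model is the identity.
#'
#' @param trace A [decay_trace()].
#' @param model An [eddy_current_model()].
#' @return The corrected [decay_trace()].
#' @export
subtract_eddy <- function(trace, model) {
  stopifnot(inherits(trace, "decay_trace"))
  corr <- eval_eddy(model, trace$time)
  z <- complex(real = Re(trace$signal) - corr, imaginary = Im(trace$signal))
  decay_trace(trace$time, z, is_quadrature = trace$is_quadrature,
              meta = trace$meta)
}

#' Detect AC-line interference spikes in a fit residual
#'
#' Constant-amplitude oscillations from AC power sources are typically
#' invisible in the raw decay but show up as spikes in the Fourier
#' transform of the residual.  The magnitude spectrum of the real-channel
#' residual is thresholded at `median + threshold_k * MAD` (MAD with the
#' normal-consistency constant 1.4826); the DC bin is excluded.  Requires
#' a uniform time grid.
#'
#' @param residual A [decay_trace()] holding a fit residual.
#' @param threshold_k Threshold in robust standard deviations (default 5).
#' @return A data frame with columns `frequency` (Hz) and `magnitude`,
#'   sorted by decreasing magnitude; zero rows when no bin exceeds the
#'   threshold.
#' @export
detect_ac_artifacts <- function(residual, threshold_k = 5) {
  stopifnot(inherits(residual, "decay_trace"))
  tt <- residual$time
  dt <- diff(tt)
  bad <- which(abs(dt - stats::median(dt)) > 1e-9 * stats::median(dt))
  if (length(bad)) {
    stop("detect_ac_artifacts: non-uniform time grid; offending intervals ",
         "at indices ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " (interpolate explicitly before spike detection)")
  }
  y <- Re(residual$signal)
  n <- length(y)
  sp <- Mod(stats::fft(y))
  half <- 2:(floor(n / 2) + 1)       # exclude DC; keep unique frequencies
  mag <- sp[half]
  freq <- (half - 1) / (n * stats::median(dt))
  thr <- stats::median(mag) + threshold_k * stats::mad(mag)
  hit <- which(mag > thr)
  out <- data.frame(frequency = freq[hit], magnitude = mag[hit])
  out[order(out$magnitude, decreasing = TRUE), , drop = FALSE]
}

#' Robust noise estimate from a fit residual
#'
#' `1.4826 * MAD` of the real-channel residual; for quadrature traces the
#' real and imaginary channels are pooled (the imaginary channel of a
#' phased trace is noise only).
#'
#' @param residual A [decay_trace()] holding a converged-fit residual.
#' @return Noise standard deviation estimate (intensity units).
#' @export
estimate_noise <- function(residual) {
  stopifnot(inherits(residual, "decay_trace"))
  v <- if (residual$is_quadrature) {
    c(Re(residual$signal), Im(residual$signal))
  } else {
    Re(residual$signal)
  }
  stats::mad(v)
}

#' Full artifact-correction pipeline for one trace
#'
#' Runs the default correction sequence before exponential fitting:
#' \enumerate{
#'   \item estimate and apply the zero-order phase (quadrature traces);
#'   \item fit the mono-exponential, fit the damped-sinusoid eddy model on
#'     the early-time residual, subtract it, and refit (one iteration);
#'   \item detect AC-line spikes in the final residual's spectrum
#'     (uniform grids);
#'   \item estimate the thermal noise level from the final residual.
#' }
#' An eddy model whose amplitude is below `min_amp_snr` times the robust
#' residual noise is considered insignificant and not subtracted, which
#' makes the pipeline idempotent on already-corrected traces.
#'
#' @param trace A [decay_trace()].
#' @param phase,eddy,ac Logical toggles for the three correction/detection
#'   stages.
#' @param eddy_window Eddy fit window end in seconds (default: larger of
#'   first 10 % of points and 5 ms).
#' @param threshold_k Spike threshold for [detect_ac_artifacts()].
#' @param min_amp_snr Minimum fitted eddy amplitude, in residual-noise
#'   units, for the subtraction to be applied (default 3).
#' @param control [fit_control()] for the exponential fits.
#' @return A list of class `corrected_trace`:
#'   \describe{
#'     \item{trace}{the corrected [decay_trace()]}
#'     \item{fit}{the final `fit_result`}
#'     \item{report}{a `correction_report` with `phase_angle`, `eddy`,
#'       `ac_spikes`, `noise_sd`, `r2_shift_phase`, `r2_shift_eddy`}
#'   }
#' @export
correct_trace <- function(trace, phase = TRUE, eddy = TRUE, ac = TRUE,
                          eddy_window = NULL, threshold_k = 5,
                          min_amp_snr = 3, control = fit_control()) {
  stopifnot(inherits(trace, "decay_trace"))
  fit_raw <- fit_monoexponential(trace, control = control)

  # stage 1: zero-order phase
  phi <- 0
  r2_shift_phase <- 0
  cur <- trace
  if (phase && trace$is_quadrature) {
    phi <- as.numeric(estimate_phase(trace))
    cur <- apply_phase(trace, phi)
    fit_phased <- fit_monoexponential(cur, control = control)
    if (fit_raw$converged && fit_phased$converged) {
      r2_shift_phase <- correction_impact(fit_raw, fit_phased)
    }
  } else {
    fit_phased <- fit_raw
  }

  # stage 2: eddy-current transient on the early-time residual
  eddy_model <- NULL
  r2_shift_eddy <- 0
  fit_final <- fit_phased
  if (eddy) {
    res1 <- residual_trace(cur, fit_phased)
    eddy_model <- tryCatch(fit_eddy_current(res1, window = eddy_window),
                           error = function(e) NULL)
    if (!is.null(eddy_model) && !isTRUE(attr(eddy_model, "flagged"))) {
      noise_now <- estimate_noise(res1)
      if (eddy_model$amplitude >= min_amp_snr * noise_now) {
        cand <- subtract_eddy(cur, eddy_model)
        fit_cand <- fit_monoexponential(cand, control = control)
        if (fit_cand$converged) {
          r2_shift_eddy <- correction_impact(fit_phased, fit_cand)
          cur <- cand
          fit_final <- fit_cand
        }
      } else {
        attr(eddy_model, "flagged") <- TRUE   # insignificant amplitude
      }
    }
  }

  # stage 3/4: AC spikes and noise from the final residual
  res2 <- residual_trace(cur, fit_final)
  ac_spikes <- NULL
  if (ac) {
    ac_spikes <- tryCatch(detect_ac_artifacts(res2, threshold_k = threshold_k),
                          error = function(e) NULL)  # non-uniform grid: skip
  }
  noise_sd <- estimate_noise(res2)

  report <- structure(
    list(phase_angle = phi, eddy = eddy_model, ac_spikes = ac_spikes,
         noise_sd = noise_sd, r2_shift_phase = r2_shift_phase,
         r2_shift_eddy = r2_shift_eddy),
    class = "correction_report"
  )
  structure(list(trace = cur, fit = fit_final, report = report),
            class = "corrected_trace")
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report>\n")
  cat(sprintf("  phase angle: %.5g rad (R2 shift %.4g%%)\n",
              x$phase_angle, x$r2_shift_phase))
  if (!is.null(x$eddy) && !isTRUE(attr(x$eddy, "flagged"))) {
    cat(sprintf("  eddy: amp %.4g, rate %.4g 1/s, freq %.5g Hz (R2 shift %.4g%%)\n",
                x$eddy$amplitude, x$eddy$decay_rate, x$eddy$frequency,
                x$r2_shift_eddy))
  } else {
    cat("  eddy: none/insignificant\n")
  }
  n_sp <- if (is.null(x$ac_spikes)) NA_integer_ else nrow(x$ac_spikes)
  cat(sprintf("  AC spikes: %s, noise sd: %.4g\n",
              ifelse(is.na(n_sp), "not assessed", n_sp), x$noise_sd))
  invisible(x)
}
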