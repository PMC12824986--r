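#' Fitting control parameters
#'
#' All numerical tolerances of the mono-exponential fitter in one object.
#'
#' @param ptol Relative parameter convergence tolerance (default 1e-10).
#' @param ftol Relative sum-of-squares convergence tolerance.
#' @param maxiter Maximum Levenberg-Marquardt iterations (default 200).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(ptol = 1e-10, ftol = 1e-10, maxiter = 200L) {
  structure(list(ptol = ptol, ftol = ftol, maxiter = as.integer(maxiter)),
            class = "fit_control")
}

#' Initial parameter guess for the offset mono-exponential model
#'
#' Seeds the nonlinear fit of `S(t) = A * exp(-alpha * t) + b`: the offset
#' `b0` is the mean of the last 5 % of points (at least 2), the amplitude
#' `A0` the first point minus `b0`, and `alpha0` comes from a log-linear
#' regression of `signal - b0` restricted to points more than 3 local noise
#' floors above the baseline.  The returned guess is always finite.
#'
#' @param trace A [decay_trace()]; the real channel is used.
#' @return Named numeric vector `c(A, alpha, b)`.
#' @export
initial_guess <- function(trace) {
  stopifnot(inherits(trace, "decay_trace"))
  y <- Re(trace$signal)
  tt <- trace$time
  n <- length(y)
  # local noise floor from successive differences (trend-free on dense
  # grids, conservative on sparse ones)
  floor_sd <- stats::mad(diff(y)) / sqrt(2)
  if (!is.finite(floor_sd)) floor_sd <- 0
  # flat-signal check: head-tail contrast against the noise floor
  k <- max(2L, ceiling(0.10 * n))
  contrast <- mean(y[seq_len(k)]) - mean(y[(n - k + 1L):n])
  if (contrast <= 4 * floor_sd / sqrt(k)) {
    stop("initial_guess: flat signal, no decay above the noise floor",
         call. = FALSE)
  }
  k_tail <- max(2L, ceiling(0.05 * n))
  b0 <- mean(y[(n - k_tail + 1L):n])
  A0 <- y[1] - b0
  excess <- y - b0
  use <- which(excess > 3 * floor_sd & excess > 0)
  alpha0 <- if (length(use) >= 2L) {
    -stats::coef(stats::lm(log(excess[use]) ~ tt[use]))[[2]]
  } else {
    NA_real_
  }
  if (!is.finite(alpha0) || alpha0 <= 0) {
    alpha0 <- 3 / (max(tt) - min(tt))
  }
  if (!is.finite(A0) || A0 == 0) A0 <- max(abs(y)) - b0
  c(A = A0, alpha = alpha0, b = b0)
}

# model and analytic Jacobian of S(t) = A exp(-alpha t) + b
.monoexp <- function(par, tt) par[1] * exp(-par[2] * tt) + par[3]

.monoexp_jac <- function(par, tt) {
  e <- exp(-par[2] * tt)
  cbind(A = e, alpha = -par[1] * tt * e, b = rep(1, length(tt)))
}

#' Fit the offset mono-exponential decay model
#'
#' Nonlinear least squares of `S_obs(t) = A * exp(-alpha * t) + b` on the
#' real channel of a (phase-corrected) decay trace.  `alpha` is the water
#' transverse relaxation rate R2(1H2O) in 1/s and `T2 = 1/alpha`.  The
#' offset `b` compensates for signals that decay to a nonzero value and is
#' always estimated.  Parameter standard errors come from the Jacobian at
#' the optimum.  Non-convergence and a non-positive decay rate are flagged
#' in the result, not raised as errors.
#'
#' @param trace A [decay_trace()] with at least 4 points.
#' @param guess Optional named start vector `c(A, alpha, b)`; defaults to
#'   [initial_guess()].
#' @param control A [fit_control()] object.
#' @param weights Optional per-point weights for weighted least squares
#'   (default: unweighted).
#' @return An object of class `fit_result` with elements `A`, `alpha`, `b`,
#'   `T2`, `param_se`, `residual_rms`, `n_points`, `converged`, `flags`.
#' @export
fit_monoexponential <- function(trace, guess = NULL, control = fit_control(),
                                weights = NULL) {
  stopifnot(inherits(trace, "decay_trace"))
  y <- Re(trace$signal)
  tt <- trace$time
  n <- length(y)
  if (n < 4L) {
    stop("fit_monoexponential: need at least 4 points for a 3-parameter fit")
  }
  if (is.null(guess)) guess <- initial_guess(trace)
  w <- if (is.null(weights)) rep(1, n) else sqrt(weights)
  res_fn <- function(par) w * (y - .monoexp(par, tt))
  jac_fn <- function(par) -w * .monoexp_jac(par, tt)
  fit <- minpack.lm::nls.lm(
    par = guess, fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      ptol = control$ptol, ftol = control$ftol, maxiter = control$maxiter)
  )
  par <- fit$par
  converged <- fit$info %in% 1:4
  flags <- character(0)
  if (!converged) flags <- c(flags, "non_converged")
  if (par[["alpha"]] <= 0) {
    converged <- FALSE
    flags <- c(flags, "nonpositive_rate")
  }
  resid <- y - .monoexp(par, tt)
  rms <- sqrt(mean(resid^2))
  J <- .monoexp_jac(par, tt) * w
  se <- rep(NA_real_, 3L)
  if (n > 3L) {
    s2 <- sum((w * resid)^2) / (n - 3L)
    cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- c("A", "alpha", "b")
  structure(
    list(A = par[["A"]], alpha = par[["alpha"]], b = par[["b"]],
         T2 = 1 / par[["alpha"]], param_se = se, residual_rms = rms,
         n_points = n, converged = converged, flags = flags,
         residuals = resid),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> alpha = %.6g 1/s (T2 = %.4g s), A = %.4g, b = %.4g\n",
    x$alpha, x$T2, x$A, x$b))
  cat(sprintf("  se(alpha) = %.3g, residual RMS = %.3g, n = %d, %s\n",
              x$param_se[["alpha"]], x$residual_rms, x$n_points,
              if (x$converged) "converged" else
                paste("NOT converged:", paste(x$flags, collapse = ","))))
  invisible(x)
}

#' Predicted decay of a fitted model
#'
#' @param fit A `fit_result`.
#' @param time Times in seconds.
#' @return `A * exp(-alpha * time) + b`.
#' @export
predict_decay <- function(fit, time) {
  stopifnot(inherits(fit, "fit_result"))
  .monoexp(c(fit$A, fit$alpha, fit$b), time)
}

#' Percent change in R2 due to a correction
#'
#' `100 * |alpha_after - alpha_before| / alpha_before`, the per-trace
#' impact of an artifact correction on the extracted relaxation rate.
#'
#' @param fit_before,fit_after Converged `fit_result` objects (or bare
#'   numeric rates).
#' @return Percent change (non-negative).
#' @seealso [rms_impact()] for the aggregate over a set of traces.
#' @export
correction_impact <- function(fit_before, fit_after) {
  a0 <- if (inherits(fit_before, "fit_result")) fit_before$alpha else fit_before
  a1 <- if (inherits(fit_after, "fit_result")) fit_after$alpha else fit_after
  if (inherits(fit_before, "fit_result") && !fit_before$converged ||
      inherits(fit_after, "fit_result") && !fit_after$converged) {
    stop("correction_impact: both fits must be converged")
  }
  if (a0 <= 0) stop("correction_impact: alpha before correction must be > 0")
  100 * abs(a1 - a0) / a0
}

#' Root-mean-square of percent changes
#'
#' Aggregates per-trace [correction_impact()] values over a set of traces.
#'
#' @param percent_changes Numeric vector of percent changes.
#' @return `sqrt(mean(percent_changes^2))`.
#' @export
rms_impact <- function(percent_changes) {
  sqrt(mean(percent_changes^2))
}

#' Departure-from-mono-exponential diagnostic
#'
#' The residual of a single-exponential fit should be pure noise for a
#' predominantly mono-exponential water decay; a residual RMS well above
#' the thermal noise level indicates more complex multi-exponential
#' relaxation.  The metric is `residual_rms / noise_sd`; values above
#' `threshold` (default 2) are flagged.
#'
#' @param fit A converged `fit_result`.
#' @param noise_sd Estimated noise standard deviation (> 0; a zero noise
#'   estimate with nonzero residual yields `Inf`, flagged).
#' @param threshold Flag threshold (default 2).
#' @return The ratio, with attributes `flagged` (logical).
#' @export
departure_metric <- function(fit, noise_sd, threshold = 2) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("departure_metric: fit must be converged")
  if (noise_sd < 0) stop("departure_metric: noise_sd must be >= 0")
  ratio <- if (noise_sd == 0) {
    if (fit$residual_rms > 0) Inf else 0
  } else {
    fit$residual_rms / noise_sd
  }
  structure(ratio, flagged = is.infinite(ratio) || ratio > threshold)
}
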