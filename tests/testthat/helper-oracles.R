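# Independent brute-force oracles used to cross-check the nonlinear fits.
# They share no code path with the estimators they validate.

# Profiled grid search for the decay rate alpha: for each candidate alpha
# the amplitude and offset are solved by linear least squares against
# (exp(-alpha*t), 1); two-stage coarse (0.01) -> fine (step) search.
oracle_grid_alpha <- function(tt, y, step = 1e-4, coarse_range = c(0.1, 20)) {
  ssr <- function(a) {
    X <- cbind(exp(-a * tt), 1)
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  coarse <- seq(coarse_range[1], coarse_range[2], by = 0.01)
  a0 <- coarse[which.min(vapply(coarse, ssr, 0))]
  fine <- seq(a0 - 0.02, a0 + 0.02, by = step)
  fine[which.min(vapply(fine, ssr, 0))]
}

# 1-D grid search minimizing the imaginary power of signal * exp(-i*phi)
# over the high-SNR window.  Imaginary power is pi-periodic, so the branch
# with a positive real-channel projection is selected.
oracle_grid_phase <- function(trace, window_frac = 0.5, step = 1e-4) {
  n <- length(trace$time)
  idx <- seq_len(max(3, ceiling(window_frac * n)))
  z <- trace$signal[idx]
  obj <- function(phis) {
    vapply(phis, function(p) sum(Im(z * exp(-1i * p))^2), 0)
  }
  coarse <- seq(-pi, pi, by = 1e-2)
  p0 <- coarse[which.min(obj(coarse))]
  fine <- seq(p0 - 0.02, p0 + 0.02, by = step)
  phi <- fine[which.min(obj(fine))]
  if (sum(Mod(z) * Re(z * exp(-1i * phi))) < 0) phi <- phi - sign(phi) * pi
  phi
}

# real-only trace on an explicit grid
make_trace <- function(tt, y) {
  decay_trace(tt, complex(real = y, imaginary = 0))
}

# clean offset mono-exponential on a uniform grid
make_decay <- function(A = 2, alpha = 3, b = 0.1, n = 200, tmax = 2) {
  tt <- seq(tmax / n, tmax, length.out = n)
  make_trace(tt, A * exp(-alpha * tt) + b)
}
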