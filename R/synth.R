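#' True relaxation model for a sample class
#'
#' The water-proton transverse relaxation rate R2(1H2O) of a dilute sample
#' responds linearly to solute concentration:
#' R2 = R2_0 + r2 * C, where r2 is the relaxivity (slope) and R2_0 the
#' solvent/buffer intercept.  Freeze/thaw stress of aluminum-adjuvant
#' suspensions irreversibly agglomerates the particles, lowering their
#' surface area and hence R2; the model represents this as a fractional
#' reduction of the whole rate.
#'
#' @param r2_0 Intercept R2_0 in 1/s; must be positive.  Default 0.35 1/s,
#'   a typical benchtop value for aqueous buffer.
#' @param relaxivity Slope r2 in (mg/mL)^-1 s^-1 (per-particle units for
#'   particle-count concentrations); must be >= 0.
#' @param freeze_thaw_delta Fractional reduction of R2 for a stressed
#'   sample, in \[0, 1).  Default 0.15 (a 15 % drop).
#' @return An object of class `relaxation_model`.
#' @export
relaxation_model <- function(r2_0 = 0.35, relaxivity = 0,
                             freeze_thaw_delta = 0.15) {
  if (r2_0 <= 0) stop("relaxation_model: r2_0 must be > 0")
  if (relaxivity < 0) stop("relaxation_model: relaxivity must be >= 0")
  if (freeze_thaw_delta < 0 || freeze_thaw_delta >= 1) {
    stop("relaxation_model: freeze_thaw_delta must be in [0, 1)")
  }
  structure(list(r2_0 = r2_0, relaxivity = relaxivity,
                 freeze_thaw_delta = freeze_thaw_delta),
            class = "relaxation_model")
}

#' Default per-class relaxation models
#'
#' Relaxivities anchor to the interlaboratory mean values for each sample
#' class: NISTmAb 8.77e-3 (mg/mL)^-1 s^-1, aluminum hydroxide (AH)
#' 0.93 (mg/mL)^-1 s^-1, aluminum phosphate (AP) 1.98 (mg/mL)^-1 s^-1.
#' ETFE particles have water-like magnetic susceptibility and a true
#' relaxivity of zero (negative control), as do buffer blanks.  Intercepts
#' default to 0.35 1/s.
#'
#' @param freeze_thaw_delta Fractional R2 reduction applied to stressed
#'   adjuvant samples (default 0.15).
#' @return Named list of [relaxation_model()] objects, one per sample class.
#' @export
default_class_models <- function(freeze_thaw_delta = 0.15) {
  list(
    mAb    = relaxation_model(relaxivity = 8.77e-3,
                              freeze_thaw_delta = freeze_thaw_delta),
    AH     = relaxation_model(relaxivity = 0.93,
                              freeze_thaw_delta = freeze_thaw_delta),
    AP     = relaxation_model(relaxivity = 1.98,
                              freeze_thaw_delta = freeze_thaw_delta),
    ETFE   = relaxation_model(relaxivity = 0),
    buffer = relaxation_model(relaxivity = 0),
    reference = relaxation_model(relaxivity = 0)
  )
}

#' Eddy-current artifact model
#'
#' Eddy currents induced in conductive parts (notably the aluminum crimp
#' caps of sealed vials) add a fast, sub-millisecond oscillatory component
#' to the echo decay, modelled as an exponentially damped sinusoid
#' `amplitude * exp(-decay_rate * t) * sin(2*pi*frequency*t + phase)`.
#'
#' @param amplitude Peak amplitude, intensity units; >= 0.
#' @param decay_rate Damping rate in 1/s; > 0 (typically >> the water R2).
#' @param frequency Oscillation frequency in Hz.
#' @param phase Phase in radians.
#' @return An object of class `eddy_current_model`.
#' @export
eddy_current_model <- function(amplitude, decay_rate, frequency, phase = 0) {
  if (amplitude < 0) stop("eddy_current_model: amplitude must be >= 0")
  if (decay_rate <= 0) stop("eddy_current_model: decay_rate must be > 0")
  structure(list(amplitude = amplitude, decay_rate = decay_rate,
                 frequency = frequency, phase = phase),
            class = "eddy_current_model")
}

#' Evaluate an eddy-current model on a time grid
#'
#' @param model An [eddy_current_model()].
#' @param time Numeric vector of times in seconds.
#' @return Numeric vector of artifact intensities.
#' @export
eval_eddy <- function(model, time) {
  stopifnot(inherits(model, "eddy_current_model"))
  model$amplitude * exp(-model$decay_rate * time) *
    sin(2 * pi * model$frequency * time + model$phase)
}

#' Laboratory acquisition profile
#'
#' Describes one laboratory's instrument and operating choices for the
#' simulator: CPMG timing (tau, echo count), scan averaging, thermal noise
#' level, and which artifacts its hardware exhibits.  Paper-faithful
#' operating ranges are tau in \[250, 6000\] us and 4--32 scans.
#'
#' @param lab_id Laboratory label.
#' @param tau Interpulse delay in seconds.
#' @param n_echoes Number of echoes (time-domain points); >= 3.
#' @param n_scans Number of co-added scans; noise standard deviation per
#'   channel scales as `noise_sd / sqrt(n_scans)`.
#' @param noise_sd Single-scan thermal noise sd per quadrature channel,
#'   intensity units.  The signal-to-noise ratio convention is
#'   `SNR = A / noise_sd` for a decay of amplitude `A`.
#' @param eddy An [eddy_current_model()] or `NULL`.
#' @param phase_offset Zero-order quadrature phase error, radians.
#' @param ac_amplitude Amplitude of a constant AC-line oscillation,
#'   intensity units (0 disables).
#' @param ac_freq AC-line frequency in Hz (default 50).
#' @param mode `"time_domain"` (uniform grid t_k = 2*tau*k) or
#'   `"frequency_domain"` (sparse hand-selected grid, see [echo_grid()]).
#' @param temperature Sample temperature, degrees Celsius.
#' @param n_fd_points Number of points for frequency-domain mode
#'   (default 17).
#' @param settled If `TRUE`, emulates a lab that failed to resuspend the
#'   adjuvant suspensions before measurement: adjuvant (AH/AP) relaxivity
#'   is multiplied by `settled_factor` before simulation.
#' @param settled_factor Relaxivity multiplier (< 1) for a settled lab.
#' @param faithful If `TRUE` (default), enforce the paper-faithful operating
#'   ranges on `tau` and `n_scans`.
#' @return An object of class `lab_profile`.
#' @export
lab_profile <- function(lab_id, tau = 500e-6, n_echoes = 1000L,
                        n_scans = 8L, noise_sd = 0.01, eddy = NULL,
                        phase_offset = 0, ac_amplitude = 0, ac_freq = 50,
                        mode = c("time_domain", "frequency_domain"),
                        temperature = 25, n_fd_points = 17L,
                        settled = FALSE, settled_factor = 0.6,
                        faithful = TRUE) {
  mode <- match.arg(mode)
  if (tau <= 0) stop("lab_profile: tau must be > 0")
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 3L) stop("lab_profile: n_echoes must be >= 3")
  n_scans <- as.integer(n_scans)
  if (n_scans < 1L) stop("lab_profile: n_scans must be >= 1")
  if (noise_sd < 0) stop("lab_profile: noise_sd must be >= 0")
  if (faithful) {
    if (tau < 250e-6 || tau > 6000e-6) {
      stop("lab_profile: paper-faithful tau must lie in [250, 6000] us; ",
           "set faithful = FALSE to override")
    }
    if (n_scans < 4L || n_scans > 32L) {
      stop("lab_profile: paper-faithful n_scans must lie in [4, 32]; ",
           "set faithful = FALSE to override")
    }
  }
  if (!is.null(eddy)) stopifnot(inherits(eddy, "eddy_current_model"))
  structure(
    list(lab_id = as.character(lab_id), tau = tau, n_echoes = n_echoes,
         n_scans = n_scans, noise_sd = noise_sd, eddy = eddy,
         phase_offset = phase_offset, ac_amplitude = ac_amplitude,
         ac_freq = ac_freq, mode = mode, temperature = temperature,
         n_fd_points = as.integer(n_fd_points), settled = isTRUE(settled),
         settled_factor = settled_factor),
    class = "lab_profile"
  )
}

#' Default seven-laboratory profile set
#'
#' Seven profiles spanning the operating ranges reported across benchtop
#' platforms: interpulse delays from 250 us to 6 ms, 4--32 scans, sample
#' temperatures 25--33 degC, echo counts from hundreds to thousands, and
#' one frequency-domain lab acquiring only 17 hand-selected points.  Some
#' labs carry an eddy-current artifact (noninvasive measurement through the
#' aluminum vial cap), a small quadrature phase offset, and/or an AC-line
#' oscillation; systematic artifact amplitudes stay below 2 % of the signal
#' amplitude.
#'
#' @param snr Signal-to-noise ratio `A / noise_sd` for unit amplitude
#'   (default 100).
#' @param artifacts If `FALSE`, all eddy/phase/AC artifacts are disabled
#'   (noise retained).
#' @return List of 7 [lab_profile()] objects.
#' @export
default_lab_profiles <- function(snr = 100, artifacts = TRUE) {
  ns <- 1 / snr
  # transients span several echoes and sit below the Nyquist frequency of
  # each lab's echo spacing, so the correction stage can resolve them
  eddy1 <- if (artifacts)
    eddy_current_model(amplitude = 0.02, decay_rate = 300,
                       frequency = 180, phase = 0.4) else NULL
  eddy2 <- if (artifacts)
    eddy_current_model(amplitude = 0.012, decay_rate = 500,
                       frequency = 350, phase = 1.1) else NULL
  ph <- function(x) if (artifacts) x else 0
  ac <- function(x) if (artifacts) x else 0
  list(
    lab_profile("Lab1", tau = 500e-6,  n_echoes = 2000L, n_scans = 16L,
                noise_sd = ns, eddy = eddy1, phase_offset = ph(0.03),
                temperature = 25),
    lab_profile("Lab2", tau = 1000e-6, n_echoes = 1500L, n_scans = 8L,
                noise_sd = ns, ac_amplitude = ac(0.004), ac_freq = 60,
                temperature = 28),
    lab_profile("Lab3", tau = 250e-6,  n_echoes = 4000L, n_scans = 32L,
                noise_sd = ns, eddy = eddy2, phase_offset = ph(-0.02),
                temperature = 26),
    lab_profile("Lab4", tau = 2000e-6, n_echoes = 1000L, n_scans = 4L,
                noise_sd = ns, mode = "frequency_domain",
                temperature = 30),
    lab_profile("Lab5", tau = 6000e-6, n_echoes = 400L,  n_scans = 16L,
                noise_sd = ns, ac_amplitude = ac(0.003), ac_freq = 50,
                phase_offset = ph(0.01), temperature = 33),
    lab_profile("Lab6", tau = 350e-6,  n_echoes = 3000L, n_scans = 8L,
                noise_sd = ns, temperature = 27),
    lab_profile("Lab7", tau = 1500e-6, n_echoes = 800L,  n_scans = 16L,
                noise_sd = ns, phase_offset = ph(0.04), temperature = 29)
  )
}

#' True transverse relaxation rate of a sample
#'
#' Evaluates R2(1H2O) = R2_0 + r2 * C, reduced by the factor
#' `(1 - freeze_thaw_delta)` for a freeze/thaw-stressed sample.
#'
#' @param model A [relaxation_model()].
#' @param concentration Concentration in mg/mL (or particle count); >= 0.
#' @param stressed Logical; has the sample experienced freeze/thaw?
#' @return Relaxation rate in 1/s.
#' @export
true_r2 <- function(model, concentration, stressed = FALSE) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(concentration < 0)) stop("true_r2: concentration must be >= 0")
  r2 <- model$r2_0 + model$relaxivity * concentration
  if (isTRUE(stressed)) r2 <- r2 * (1 - model$freeze_thaw_delta)
  r2
}

#' Echo time grid for a lab profile
#'
#' Time-domain CPMG refocuses echo k at t_k = 2 * tau * k, giving a uniform
#' grid of `n_echoes` points.  Frequency-domain mode emulates the sparse
#' hand-selected sampling of spectrally processed CPMG data: `n_fd_points`
#' (default 17) log-spaced times over the same span.
#'
#' @param profile A [lab_profile()].
#' @return Strictly increasing numeric vector of times in seconds.
#' @export
echo_grid <- function(profile) {
  stopifnot(inherits(profile, "lab_profile"))
  if (profile$mode == "time_domain") {
    2 * profile$tau * seq_len(profile$n_echoes)
  } else {
    t1 <- 2 * profile$tau
    tn <- 2 * profile$tau * profile$n_echoes
    exp(seq(log(t1), log(tn), length.out = profile$n_fd_points))
  }
}

#' Simulate one CPMG decay trace
#'
#' Forward-simulates the observed echo decay
#' `S(t) = A * exp(-R2 * t) + b` plus the configured artifact terms, then
#' applies the lab's quadrature phase rotation and adds complex Gaussian
#' thermal noise:
#' `signal(t) = (S(t) + eddy(t) + ac(t) + eps_re(t) + i * eps_im(t)) *
#' exp(i * phase_offset)`, with `eps` of standard deviation
#' `noise_sd / sqrt(n_scans)` per channel.  Fully reproducible from `seed`;
#' the caller's RNG state is left untouched.
#'
#' @param model A [relaxation_model()] for the sample's class.
#' @param concentration Sample concentration (mg/mL or particle count).
#' @param stressed Logical freeze/thaw flag.
#' @param profile A [lab_profile()].
#' @param amplitude Signal amplitude `A` at t = 0 (intensity units).
#' @param offset Baseline offset `b` (intensity units).
#' @param seed Integer seed (mandatory).
#' @param sample_code Optional vial code stored in the trace metadata.
#' @return A [decay_trace()].
#' @export
simulate_decay <- function(model, concentration, stressed, profile,
                           amplitude = 1, offset = 0.02, seed,
                           sample_code = NA_character_) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(profile, "lab_profile"))
  if (missing(seed)) stop("simulate_decay: seed is mandatory")
  r2 <- true_r2(model, concentration, stressed)
  tt <- echo_grid(profile)
  clean <- amplitude * exp(-r2 * tt) + offset
  art <- numeric(length(tt))
  if (!is.null(profile$eddy)) art <- art + eval_eddy(profile$eddy, tt)
  if (profile$ac_amplitude != 0) {
    art <- art + profile$ac_amplitude * sin(2 * pi * profile$ac_freq * tt)
  }
  sd_eff <- profile$noise_sd / sqrt(profile$n_scans)
  noise <- withr::with_seed(as.integer(seed), {
    complex(real = stats::rnorm(length(tt), 0, sd_eff),
            imaginary = stats::rnorm(length(tt), 0, sd_eff))
  })
  z <- (complex(real = clean + art, imaginary = 0) + noise) *
    exp(1i * profile$phase_offset)
  meta <- acquisition_meta(lab_id = profile$lab_id, tau = profile$tau,
                           n_scans = profile$n_scans,
                           temperature = profile$temperature,
                           mode = profile$mode, sample_code = sample_code)
  decay_trace(tt, z, is_quadrature = any(Im(z) != 0), meta = meta)
}

# per-trace seed stream: study seed plus a (profile, entry) counter,
# kept below 2^31 - 1
.trace_seed <- function(seed, profile_idx, entry_idx) {
  as.integer((as.numeric(seed) + 1000003 * profile_idx + 97 * entry_idx) %%
               2147483647)
}

#' Simulate a whole multi-laboratory study
#'
#' Generates one decay trace per (lab profile, manifest entry) pair.  Each
#' trace draws from its own RNG stream derived from the study seed and the
#' (profile index, entry index) counter, so the study is reproducible as a
#' whole and per trace.  A `settled` profile (a lab that skipped sample
#' resuspension) has its adjuvant (AH/AP) relaxivities multiplied by the
#' profile's `settled_factor` before simulation.
#'
#' @param models Named list of [relaxation_model()] per sample class; every
#'   class in the manifest must be present.
#' @param manifest A `study_manifest` (see [load_manifest()]).
#' @param profiles List of [lab_profile()] objects.
#' @param seed Integer study seed.
#' @param amplitude,offset Signal amplitude and baseline passed to
#'   [simulate_decay()].
#' @return A list of [decay_trace()] objects named `"<lab_id>/<sample_code>"`.
#' @export
simulate_study <- function(models, manifest, profiles, seed,
                           amplitude = 1, offset = 0.02) {
  stopifnot(inherits(manifest, "study_manifest"))
  missing_cls <- setdiff(unique(manifest$sample_class), names(models))
  if (length(missing_cls)) {
    stop("simulate_study: no relaxation model for class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  out <- vector("list", length(profiles) * nrow(manifest))
  nms <- character(length(out))
  k <- 0L
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    for (e in seq_len(nrow(manifest))) {
      entry <- manifest[e, ]
      mod <- models[[entry$sample_class]]
      if (prof$settled && entry$sample_class %in% c("AH", "AP")) {
        mod <- relaxation_model(
          r2_0 = mod$r2_0,
          relaxivity = mod$relaxivity * prof$settled_factor,
          freeze_thaw_delta = mod$freeze_thaw_delta
        )
      }
      k <- k + 1L
      out[[k]] <- simulate_decay(mod, entry$concentration, entry$stressed,
                                 prof, amplitude = amplitude,
                                 offset = offset,
                                 seed = .trace_seed(seed, p, e),
                                 sample_code = entry$sample_code)
      nms[k] <- paste0(prof$lab_id, "/", entry$sample_code)
    }
  }
  names(out) <- nms
  out
}
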