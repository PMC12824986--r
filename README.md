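# wnmr

Analysis toolkit for **water-proton NMR relaxometry (wNMR)** on benchtop
time-domain instruments, aimed at pharmaceutical quality control of
biologics and vaccines: monoclonal antibody solutions, aluminum-adjuvant
suspensions (Alhydrogel/AH and Adju-Phos/AP), and inert reference
particles.  The measurement is non-invasive — the sealed product vial goes
into the magnet — and the readout is the transverse relaxation rate of the
solvent water protons, R₂(¹H₂O), obtained from a CPMG echo train.

The package covers the full chain from raw echo decays to an
interlaboratory study report:

* **I/O** for the CSV dialects benchtop relaxometers produce (two-column
  real or three-column quadrature records) and for blinded-study manifests;
* **artifact correction** for the three systematic error sources of
  low-field vial measurements — zero-order quadrature phase deviations,
  eddy-current transients induced in the aluminum crimp cap, and AC-line
  oscillations revealed as spikes in the residual spectrum;
* **decay fitting** of the offset mono-exponential model;
* **study statistics**: per-lab relaxivity calibrations, interlaboratory
  span and coefficient of variation, freeze/thaw outlier detection, and
  zero-slope negative-control tests;
* a **synthetic multi-laboratory study generator**, so the entire analysis
  runs and can be validated with no external data.

## The model

A CPMG echo train refocuses echo *k* at *t* = 2τk (τ the interpulse
delay).  The echo envelope of a predominantly aqueous sample decays
mono-exponentially with an offset:

    S_obs(t) = A · exp(−α t) + b,        α ≡ R₂(¹H₂O) = 1/T₂

fitted here by Levenberg–Marquardt least squares with analytic Jacobian.
R₂(¹H₂O) responds linearly to solute concentration *C*:

    R₂(¹H₂O) = R₂,₀(¹H₂O) + r₂ · C

where the slope r₂ is the **relaxivity** of the solute ((mg/mL)⁻¹ s⁻¹).
Freeze/thaw damage of aluminum adjuvants irreversibly agglomerates the
particles and lowers R₂; a stressed vial is compared to its unstressed
mate through

    %R₂ change = [1 − R₂(frozen)/R₂(unfrozen)] · 100 %

and flagged against the larger of a 10 % detection line and the lab's own
calibration-residual error band.  Interlaboratory agreement is summarized
by the span (max − min) of per-lab relaxivities and CV = (σ/μ)·100 %.

## Worked example

Simulate one adjuvant measurement from a lab whose hardware shows an
eddy-current transient and a small phase error, correct and fit it:

```r
library(wnmr)

profile <- lab_profile("Lab1", tau = 500e-6, n_echoes = 2000, n_scans = 16,
                       noise_sd = 0.01,
                       eddy = eddy_current_model(amplitude = 0.02,
                                                 decay_rate = 300,
                                                 frequency = 180,
                                                 phase = 0.4),
                       phase_offset = 0.03)
model <- relaxation_model(r2_0 = 0.35, relaxivity = 0.93)   # AH-like
trace <- simulate_decay(model, concentration = 1.25, stressed = FALSE,
                        profile, seed = 7)
corrected <- correct_trace(trace)
corrected$report
#> <correction_report>
#>   phase angle: 0.029946 rad (R2 shift 0.0009115%)
#>   eddy: amp 0.04446, rate 465.4 1/s, freq 120.17 Hz (R2 shift 0.01017%)
#>   AC spikes: 0, noise sd: 0.002433
corrected$fit
#> <fit_result> alpha = 1.51509 1/s (T2 = 0.66 s), A = 1, b = 0.02045
#>   se(alpha) = 0.00102, residual RMS = 0.0025, n = 2000, converged
```

The estimated phase (0.0299 rad) matches the configured 0.03 rad offset,
and the fitted rate 1.515 s⁻¹ recovers the true
R₂ = 0.35 + 0.93 × 1.25 = 1.5125 s⁻¹ to 0.2 %.

A complete blinded study — 7 lab profiles × the 24-vial kit (mAb, AH, AP,
ETFE series plus one freeze/thaw-stressed AH and AP vial) — runs through
simulation, correction, fitting and aggregation in one call:

```r
result <- run_pipeline(pipeline_config(seed = 1))
result$report
#> <study_report>
#>   interlab dispersion (slope units):
#>     AH      n=7  mean=0.9286  span=0.01409  CV=0.528%
#>     AP      n=7  mean=1.98  span=0.01265  CV=0.215%
#>     ETFE    n=7  mean=1.278e-09  span=5.958e-08  CV=1.65e+03%
#>     mAb     n=7  mean=0.008794  span=0.0001784  CV=0.683%
#>   freeze/thaw assessments: 14, flagged: 14
```

Per-lab relaxivity means land on the generating class values (mAb
8.77 × 10⁻³, AH 0.93, AP 1.98 (mg/mL)⁻¹ s⁻¹), the ETFE negative control
reads as zero slope (its huge CV is the expected behavior of a
zero-mean statistic), and every lab flags both stressed vials:

```r
subset(result$report$outliers, sample_class == "AH",
       select = c(lab_id, ratio, percent_change, flagged))
#>    lab_id     ratio percent_change flagged
#> 1    Lab1 0.8498918       15.01082    TRUE
#> 3    Lab2 0.8507948       14.92052    TRUE
#> 5    Lab3 0.8502806       14.97194    TRUE
#> 7    Lab4 0.8664594       13.35406    TRUE
#> 9    Lab5 0.8503538       14.96462    TRUE
#> 11   Lab6 0.8487237       15.12763    TRUE
#> 13   Lab7 0.8502788       14.97212    TRUE
```

See `vignettes/wnmr-methods.Rmd` for the full account of the model,
artifact treatments, generator design and numerical choices.

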