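---
title: "Methods: CPMG relaxometry correction, fitting and study analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CPMG relaxometry correction, fitting and study analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and its model

Water-proton NMR relaxometry (wNMR) reads out the transverse relaxation
rate of the solvent, R₂(¹H₂O), from a CPMG echo train acquired on a
benchtop time-domain instrument, usually without opening the product
vial.  Echo *k* is refocused at *t* = 2τk, where τ is the interpulse
delay.  For predominantly aqueous pharmaceutical samples the echo
envelope is modelled as an offset mono-exponential,

$$S_{obs}(t) = A\,e^{-\alpha t} + b, \qquad \alpha \equiv R_2(^1\!H_2O) = 1/T_2,$$

where $A$ is the echo intensity at $t = 0$ and $b$ compensates for
signals that decay to a nonzero value.  The offset is always estimated,
never pinned to zero.  The solute dependence is linear,
$R_2 = R_{2,0} + r_2 C$, with relaxivity $r_2$ the calibration slope per
laboratory and sample class.

Key assumptions: a single dominant water relaxation component (the
residual-to-noise ratio, `departure_metric()`, diagnoses violations);
time measured in seconds from the 90° excitation pulse; concentration in
mg/mL (particle counts for the ETFE control).

# Artifact corrections

Three artifact classes are handled before fitting, in a fixed order.

**Zero-order phase.**  Imperfect 180° pulses accumulate a small rotation
of signal from the real into the imaginary quadrature channel.  The
phase is estimated in closed form, $\hat\varphi = \operatorname{atan2}
(\sum w\,\mathrm{Im}\,z, \sum w\,\mathrm{Re}\,z)$ with $w = |z|$ over
the first half of the points (the high-SNR window), and removed by
multiplying with $e^{-i\hat\varphi}$.  Only a global (zero-order) phase
is considered: echo-train data has no frequency axis, so a first-order
term has no meaning here.  Fitting then uses the real channel rather
than the magnitude; the magnitude of complex noise has a positive mean
(Rician floor) that biases the offset, a bias the test suite
demonstrates directly.

**Eddy-current transient.**  Conductive parts — notably the aluminum
crimp cap of a sealed vial — support eddy currents that add a fast,
oscillatory component to the early echoes.  It is modelled as an
exponentially damped sinusoid
$a\,e^{-\lambda t}\sin(2\pi f t + \phi)$
fitted to the residual of the current exponential fit on an early-time
window (the larger of the first 10 % of points and $t < 5$ ms; the
transient is much faster than the water decay).  The fit is
Levenberg–Marquardt with multi-start: candidate frequencies come from
the dominant FFT bin of the window residual ± 2 bins, plus the dominant
bins of a short early sub-window where a fast transient stands out
against slower interference; two damping starts (slow and fast) and two
phase starts are tried per frequency.  Two guards make the stage safe:

* *Transient criterion.*  A solution damped more slowly than
  $2/\mathrm{span}$ of the window does not die off within the window; it
  describes persistent interference (AC pickup), not an eddy current,
  and is rejected during model selection.
* *Significance guard.*  A fitted amplitude below 3 robust residual
  noise standard deviations is insignificant and is not subtracted.
  This is what makes the whole correction pipeline idempotent: on an
  already-corrected trace the refitted "transient" is noise-level and is
  skipped, so a second pass changes R₂ by far less than 0.01 %.

One fit → subtract → refit iteration is the default, matching the small
size of the artifact; the window and iteration behavior are arguments.

**AC-line oscillation.**  Constant-amplitude power-line interference is
invisible in the raw decay but appears as sharp spikes in the magnitude
spectrum of the fit residual.  Bins exceeding
median + $k$·MAD ($k = 5$ by default, MAD with the normal-consistency
constant 1.4826) are reported, DC excluded, strongest first.  Spikes are
*reported, not filtered*, by default: being small and centred at zero
they perturb the exponential fit like thermal noise of equal power (a
property the test suite verifies), so removal is not required for an
accurate R₂.  Detection requires a uniform grid; non-uniform grids are
refused explicitly rather than silently resampled.

Noise is estimated as 1.4826·MAD of the final residual, pooling both
quadrature channels when present.

# Decay fitting

`fit_monoexponential()` runs Levenberg–Marquardt on $(A, \alpha, b)$
with analytic Jacobian, relative tolerances $10^{-10}$ and a 200
iteration budget; standard errors come from the Jacobian at the optimum.
Non-convergence and non-positive rates are *flagged*, not thrown, so a
batch run always yields a complete table.  The initial guess takes $b_0$
from the mean of the last 5 % of points, $A_0$ from the first point, and
$\alpha_0$ from a log-linear regression of the baseline-subtracted
signal restricted to points above 3 noise floors.  The noise floor is
the scaled MAD of successive differences — trend-free on dense grids and
conservative on sparse ones — and a head-minus-tail contrast against
that floor rejects flat (fully decayed or empty) signals before any
fitting.  Weighting is unweighted by default, with optional
inverse-variance weights.

The fit is validated against an independent brute-force oracle: a
profiled grid search over $\alpha$ (amplitude and offset solved linearly
at each grid point, coarse 0.01 then fine $10^{-4}$ s⁻¹ resolution)
must agree with the nonlinear optimum to the grid resolution on seeded
instances.  The phase estimator is likewise checked against a 1-D grid
search of the imaginary power (which is π-periodic; the branch with a
positive real projection is taken).

# Study aggregation

Per-lab, per-class relaxivity calibrations use ordinary least squares on
the unstressed concentration series; stressed and settled vials never
enter a calibration.  The reported `rmsd` — the RMS of measured R₂ minus
the line — is the per-lab error estimate.  Dispersion across labs is
summarized by the span (max − min) of slopes and CV = (σ/μ)·100 %,
with the sample (n−1) standard deviation by default and the population
convention behind a flag, since either convention is defensible and the
choice is stated rather than hidden.

**Freeze/thaw outliers.**  A stressed vial is compared to its unstressed
mate via the ratio and percent change
$[1 - R_2^{frozen}/R_2^{unfrozen}]\cdot 100\,\%$ and flagged when the
absolute change exceeds the larger of the fixed 10 % detection line and
the lab's own band, $100\,\mathrm{rmsd}/R_2^{unfrozen}$ (the calibration
RMSD propagated to the ratio scale at first order).  The direction is
recorded because an apparent *increase* (e.g. from an unmixed unstressed
mate) is as diagnostic as a decrease.

**Negative control.**  ETFE particles match water's magnetic
susceptibility, so their true relaxivity is zero.  The zero-slope test
declares a calibration consistent with zero when
$|\mathrm{slope}| \le 2\,\mathrm{se}$.  When per-point measurement
errors are available the slope error is propagated from them; with only
5 concentrations the residual-based OLS error has 3 degrees of freedom
and a $2\sigma$ rule on it covers the truth only ~86 % of the time,
while the propagated error is a direct estimate whose $2\sigma$ rule has
the intended ~95 % behavior.  The residual-based error remains the
fallback when no measurement errors accompany the points.

Duplicate (lab, vial) submissions — a real failure mode of blinded
studies — keep the later measurement and log the anomaly; a stressed
vial without an unstressed mate is reported unassessable rather than
fatal.

# The synthetic study generator

The generator replaces the shipped sample kit so the full analysis is
exercisable end to end.  It emulates:

* the 24-vial kit: 6 AH (0.31–10 mg/mL) and 5 AP (0.31–5 mg/mL)
  concentrations, one stressed AH and AP vial at 1.25 mg/mL, 5 NISTmAb
  concentrations (1–100 mg/mL) plus buffer, and 5 ETFE particle counts;
* seven lab profiles spanning the reported operating ranges — τ from
  250 µs to 6 ms, 4–32 scans, 25–33 °C, echo counts from hundreds to
  thousands, and one frequency-domain lab acquiring only 17
  hand-selected points (emulated as log-spaced sparse sampling of the
  same mono-exponential, since only the point-count consequence is
  analytically relevant);
* the three artifact classes, with complex Gaussian noise of standard
  deviation `noise_sd/sqrt(n_scans)` per channel and the convention
  SNR = A/noise_sd.

Class relaxivities default to the interlaboratory means — mAb
8.77 × 10⁻³, AH 0.93, AP 1.98 (mg/mL)⁻¹ s⁻¹ — which are the available
anchors; intercepts are not reported anywhere, so R₂,₀ = 0.35 s⁻¹ is a
package convention typical of aqueous buffer at benchtop fields, and is
configurable.  The freeze/thaw reduction defaults to 0.15 so that the
10 % detection line is genuinely exercised (a 15 % true change must be
seen above a 10 % threshold through measurement noise).  Artifact
amplitudes respect the observed regime of small systematic distortions:
eddy amplitudes ≤ 2 % of the signal amplitude, phase offsets ≤ 0.05 rad,
AC amplitudes below the thermal noise.  The default eddy transients are
chosen to be *resolvable on their lab's echo grid* (several echoes long,
below the Nyquist frequency of the echo spacing): a transient that dies
before the first echo is invisible in the data and uncorrectable by any
method.  A `settled` profile multiplies adjuvant relaxivities by 0.6
before simulation, reproducing a lab that skipped resuspension; its
calibration slope then separates from compliant labs, which is how the
study's non-inverting labs were identified.

Per-trace seeds derive from the study seed plus a (profile index, entry
index) counter, so studies are reproducible as a whole and per trace,
and any single trace can be regenerated in isolation.

What the generator does **not** model — and hence what passing tests do
not demonstrate about real data: between-lab systematic biases in R₂
(calibration, temperature and field-strength dependences), so the
synthetic interlaboratory CV is measurement-noise-limited and far
smaller than the dispersion of a real study; sedimentation kinetics
during acquisition; B₀/B₁ inhomogeneity; multi-exponential relaxation
of non-aqueous components; and shipping effects.  Conclusions about
*detectability* (freeze/thaw flags, zero-slope verdicts, artifact
impact bounds) transfer; conclusions about absolute interlab dispersion
do not.

# Numerical choices and degenerate inputs

* Time unit fixed to seconds at the I/O boundary; `time_unit` rescales
  ms/µs exports on read.  Delimiters auto-detected among comma,
  semicolon and tab; one optional header row detected by a non-numeric
  first row; out-of-order rows are sorted and flagged instead of
  rejected.
* A two-column write of a quadrature trace is refused unless an explicit
  real/magnitude reduction policy is given.
* Negative fitted eddy amplitudes and frequencies are folded into the
  phase, so reported models have a canonical $(a \ge 0, f \ge 0,
  \phi \in (-\pi, \pi])$ form.
* `correction_impact()` demands converged fits and positive baseline
  rates; aggregate impacts use the RMS of percent changes.
* Report display rounds to 3 significant figures; all tests compare
  unrounded values at explicit tolerances.

# Problem sizes

The test and acceptance runs use, as the package's own validation
conditions: 100 traces per lab profile for parameter recovery at
SNR 100; 24 traces per artifact sweep for correction-impact bounds;
100 seeds for the negative-control and false-positive calibrations; 20
seeded instances for each brute-force oracle comparison; and the full
7 × 24 study for end-to-end freeze/thaw detection.

# Known limitations

Single-component exponential model only (no inverse-Laplace or
stretched-exponential alternatives); zero-order phase only; constant
baseline only; eddy correction assumes one dominant transient; spike
detection requires uniform sampling.  These match the scope of the
analysis the package implements.
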