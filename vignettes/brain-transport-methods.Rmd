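---
title: "Measuring brain diffusion and clearance from photometry traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain diffusion and clearance from photometry traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainclear)
```

## The measurement problem

Whether sleep speeds up or slows down the clearance of solutes from the
brain is usually probed by injecting a fluorescent tracer and watching
where it goes. brainclear implements the biophysical models needed to turn
such recordings into numbers: an effective diffusion coefficient $D$ of
the tracer in tissue, and a clearance half-time $\tau$ describing how fast
the tracer leaves the brain altogether. Two experimental designs are
covered:

* **Photobleaching (FRAP) diffusimetry.** With the tracer at a local
  steady state, a brief intense light pulse bleaches the dye in a small
  volume around an optical fiber; fluorescence then recovers as unbleached
  dye diffuses back in. The recovery time course depends on $D$.
* **Arrival-curve clearance measurement.** A small bolus is injected deep
  in the brain (caudate putamen) and fluorescence is recorded a few
  millimetres away (frontal cortex). Diffusion alone predicts a specific
  rise-and-fall curve; clearance depresses it in a characteristic,
  fittable way.

Because the animal recordings behind these designs are not redistributable,
the package ships seeded generators (`sim_frap_trace()`,
`sim_clearance_trace()`, `sim_histology_profile()`,
`sim_sleep_features()`) that forward-simulate every signal the fitters
consume. The generators share the fitters' mean-model code paths exactly,
which is what makes round-trip identifiability tests meaningful.

## The Gaussian volume-source model

Both designs start from the same idealisation: at $t = 0$ the relevant dye
(bleached dye in FRAP, injected dye in the clearance design) occupies a
hemispherical Gaussian of standard deviation $\sigma$,
$Q(s) = Q(0)\exp(-s^2/2\sigma^2)$. Free diffusion then gives

$$C(r,t) = C(0,0)\left[1 + \frac{2Dt}{\sigma^2}\right]^{-3/2}
  \exp\!\left(\frac{-r^2}{4Dt + 2\sigma^2}\right),$$

implemented in `concentration_profile()`. Everything else derives from
this kernel:

* `hemisphere_moles()` integrates $2\pi r^2 C(r,t)$ over a detection
  hemisphere of radius $R$, giving the erf-based closed form whose decay
  is the FRAP observable. The recorded intensity is
  $I(t) = I_\infty - (I_\infty - I_0)\,M(t)/M(0)$
  (`recovery_intensity()`).
* `hemisphere_moles_flow()` adds a bulk flow of speed $v$; the resulting
  integral has no closed form and is evaluated by adaptive quadrature.
* `clearance_concentration()` multiplies the kernel by the survival
  factor $\tau/(t+\tau)$, so the fraction cleared is
  $100\,t/(t+\tau)$ (`clearance_percent()`).
* `peak_arrival_time()` gives the closed-form peak time
  $(r^2/3 - \sigma^2)/2D$ of the arrival curve; at fixed distance it
  depends only on $D$, which is why the observed 2--3 h peak pins the
  in vivo diffusion coefficient.
* `slab_concentration()` is the independent "direct" diffusimetry
  reference: efflux from a gel sheet sealed on one face, the standard
  cosine-series solution.
* `tortuosity()` and `stokes_einstein_correct()` convert between tissue
  and free-solution coefficients: $\lambda = \sqrt{D_{aq}/D}$ after
  bringing bench-top (20 °C) values to body temperature via
  $D \propto T/\eta(T)$ with a hard-coded handbook water-viscosity table
  ($\eta(20) = 1.0016$, $\eta(37) = 0.6913$ mPa·s, linear interpolation
  at 5 °C resolution).

Units are fixed package-wide to µm, s and µm² s⁻¹; concentration and
intensity units are arbitrary and cancel in every fitted quantity except
the calibration slope.

```{r chain}
d_aq_37 <- stokes_einstein_correct(136, t_from = 20, t_to = 37)
tortuosity(d_tissue = 32.1, d_aq = d_aq_37) # ~2.5 in cortex

d_small <- stokes_einstein_correct(295, 20, 37) / 1.4^2
peak_arrival_time(r = 3335, d = d_small, sigma = 250) / 3600 # hours
```

## Fitting choices

`fit_frap()` and `fit_clearance()` are bounded Levenberg–Marquardt least
squares (via minpack.lm) with multi-start: five log-spaced starts for $D$
spanning 1–1000 µm² s⁻¹, crossed with three log-spaced starts
(10³–10⁵ s) for $\tau$; the lowest residual sum of squares wins. The
multi-start grid exists because the arrival-curve model has a shallow
$D$–$\tau$ trade-off at early times. Choices a user may care about:

* **Intensity anchors.** $I_\infty$ defaults to the mean of the final
  5 min before the bleach; $I_0$ to the first post-bleach sample. Both
  can instead be refined jointly with $D$ (`free_intensities = TRUE`).
  Because the anchors are estimated from the trace, the fitted $D$ is
  invariant to affine transforms of the intensity scale.
* **Early-time mask.** Clearance fits drop the first 20 min by default:
  dye reaching the cortex through the ventricles produces an early bump
  the parenchymal model does not describe. Configurable via
  `mask_early`.
* **Clearance at the peak** is evaluated on the fitted curve's own
  maximum (located by `optimize()`), not on the noisy data's argmax.
* **Identifiability.** A fitted $\tau$ whose linearised 95% interval
  spans more than three decades is flagged (`identifiable = FALSE`) and
  warned about, never silently returned.
* **Uncertainty.** Reported intervals are linearised (residual
  covariance); the `bca_ci()` machinery can bootstrap any derived
  statistic when the linearisation is suspect.

`baseline_correct()` implements the ratiometric cubic-spline baseline
correction used for in vivo FRAP: the slowly declining baseline
(about 6% per hour as the injected depot washes out) is fitted by least
squares with interior knots every 60 min on samples outside every
bleach/recovery window plus a 15-min guard, and the trace is divided by
it (subtraction is available). Excluded samples provably cannot influence
the spline. Fits require at least 30 min of baseline coverage.

`fit_gaussian_profile()` (histology) fits amplitude, centre, width and a
constant baseline with an analytic Jacobian; widths are reported as
standard deviations. The expected width of a profile killed at time $t$
is $\sqrt{\sigma^2 + 2Dt}$, which is how the histology data cross-check
the photometry-derived $D$. The fitter deliberately avoids
finite-difference Jacobians: profiles centred near the injection origin
put the centre parameter at $\approx 0$, where relative-step
differencing degenerates.

## What the generators emulate, and what they do not

The generators reproduce the statistical structure the fitters assume:
exact model mean curves, multiplicative Gaussian noise with fixed
coefficient of variation (1% for FRAP, 2% for arrival curves — lock-in
photometry noise tracks signal), the ~6%-per-hour baseline decline, a
relative histology background (10% of the profile peak), and
state-conditional log-normal EEG/EMG features with wake/NREM/REM means
separated by ≥3 within-state SDs on their discriminating axes. Default
study conditions: FRAP gel example $D = 136$ µm² s⁻¹ with
$\sigma = R = 150$ µm; clearance condition $D = 230.7$ µm² s⁻¹ (the
37 °C free-solution value 452.2 divided by $1.4^2$), $\sigma = 250$ µm,
$r = 3335$ µm, and $\tau = 2600$ s, which places ~75% clearance at the
curve's peak — the undisturbed-clearance (saline) regime.

They do **not** emulate ventricular transit (the early-time bump), heavy-
tailed or correlated photometry noise, movement artefacts, slice damage,
or realistic EEG spectra (the optional `sim_sleep_signals()` waveform
mode places power in the right bands and nothing more). Passing
round-trip tests therefore demonstrates estimator correctness and
numerical identifiability under the stated noise model — not robustness
to every pathology of real recordings.

## Sleep scoring

`compute_sleep_features()` follows the standard pipeline: EEG high-pass
0.5 Hz, EMG band-pass 1–50 Hz (zero-phase Butterworth), then per-5-s-bin
delta (1–4 Hz) and theta (5–10 Hz) Welch band powers (2-s Hann segments,
50% overlap), their ratio, and EMG RMS. The 0.5–4 Hz delta variant used
for slow-wave-activity correlations is available via `delta_band`.

`score_sleep()` fits a 3-component full-covariance Gaussian mixture
(mclust) to standardised log features and maps components by a fixed
rule — highest EMG mean is Wake; of the rest, higher theta/delta is REM.
One wrinkle: the log ratio is an exact linear combination of the log band
powers, so including it in the mixture would make every within-component
covariance singular by construction. The mixture is therefore fitted on
the three independent features and the ratio enters through the mapping
rule (posterior-weighted component means). There is no temporal model:
permuting bins permutes labels identically. This mirrors the practice of
GMM pre-scoring followed by manual confirmation; transition constraints
are out of scope.

## Estimation statistics

`bca_ci()` implements the bias-corrected and accelerated bootstrap:
$z_0$ from the fraction of resampled statistics below the estimate,
acceleration from jackknife skewness, and endpoint quantiles interpolated
on the normal scale. With both corrections zero it reduces to the
percentile interval; a degenerate resample distribution returns a flagged
zero-width interval. `paired_mean_difference()` retains the full
resample distribution for the "distribution of likelihood" panels, and
`holm_adjust()` delegates to `stats::p.adjust`. The study convention is
5,000 resamples; the test suite's coverage simulation uses 1,000
resamples over 1,000 Monte-Carlo replicates, which resolves coverage to
about ±1.5% while keeping the default run to seconds.

## Numerical choices

* Flow quadrature: `stats::integrate`, relative tolerance 10⁻⁹, absolute
  10⁻¹², with a warned fallback to a 10⁴-point Simpson rule.
* Slab series: truncated when the next term falls below $10^{-12}C_0$ or
  at 200 terms; at $t = 0$ the alternating series then carries its
  $\sim 1.6\times10^{-3}$ Leibniz tail, which is immaterial at any
  $t > 0$ of practical interest.
* Bleach-window spread: the 30-s bleach inflates the optical $\sigma$;
  `bleach_spread_sigma()` time-averages the spreading profile over the
  window and refits a Gaussian. The inflation is bounded by
  $\sqrt{\sigma^2 + 2D\Delta t}$ and stays under 8% for the geometries
  here.
* Peak time returns 0 (monotone-decay regime) when $r^2 \le 3\sigma^2$
  rather than erroring: a detector inside the source simply sees decay.
* Degenerate inputs fail loudly: non-finite times, non-positive widths,
  calibration slopes ≤ 0, insufficient baseline coverage, and mixtures on
  fewer than 50 bins are all explicit errors.

## Problem sizes

The shipped tests run the full pipeline at desk scale: 1-h FRAP
recoveries at 1 Hz, 8-h arrival curves at 0.2 Hz, 20-seed recovery
studies at the generators' stated noise, a 10⁷-sample Monte-Carlo check
of the flow quadrature, a Crank–Nicolson cross-check of the slab series
over $Dt/L^2 \in [0.01, 2]$, 600-bin sleep-scoring runs over 10 seeds,
and the 1,000-replicate bootstrap coverage study. The whole suite
completes in about a minute.

## Known limitations

* The in vivo bleached-volume $\sigma$ is a required user input; the
  package cannot estimate it from a recovery trace alone (only
  $D/\sigma^2$-like combinations are identifiable there).
* The flow model is the stated radial-advection form, not a full 3D
  advected-Gaussian hemisphere integral; its Monte-Carlo validation
  checks the quadrature of that stated model.
* Single-compartment clearance with saturating kinetics is assumed;
  multi-compartment (ventricle/CSF) transport is out of scope.
* Two fiber-to-cannula distances circulate (calculated 3.335 mm;
  coordinate-derived 3.3530 mm); `fiber_cannula_distances()` exposes
  both and the package defaults to 3335 µm without resolving the
  discrepancy. Postmortem measurements should be preferred when
  available.
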