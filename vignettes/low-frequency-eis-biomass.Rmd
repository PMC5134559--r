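---
title: "Low-frequency impedance spectroscopy as a biomass soft sensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-frequency impedance spectroscopy as a biomass soft sensor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfeis)
```

## The measurement and its model

A low-frequency electrochemical impedance probe measures the complex
impedance $Z(\omega)$ of a cultivation broth between two electrodes over a
sweep from 1 MHz down to 0.1 Hz. In this band the response is dominated by
the electrode double layer. Cells adsorbed on or near the electrode deform
the ionic cloud around their membranes (the $\alpha$-dispersion), so the
double-layer capacitance grows with viable cell concentration. Because the
double layer dominates, the signal is far less sensitive to stirring and
aeration than conventional $\beta$-dispersion capacitance probes operating
at $10^4$–$10^7$ Hz.

`lfeis` implements the data-processing chain of such a sensor: an
equivalent-circuit forward model, a complex nonlinear least-squares (CNLS)
estimator for the circuit parameters, a linear calibration from the fitted
double-layer parameter to dry cell weight (DCW), and a synthetic-data
generator that stands in for the instrument.

The equivalent circuit is, in series:

* $L_\mathrm{setup}$, $R_\mathrm{offset}$ — inductance and resistance
  correcting for cabling and cell geometry;
* $R_\mathrm{media} \parallel C_\mathrm{media}$ — the media contribution,
  visible as a high-frequency shoulder;
* $R_\mathrm{dl} \parallel \mathrm{CPE}_\mathrm{dl}$ — the double layer,
  a resistance in parallel with a constant-phase element.

The CPE has impedance

$$Z_\mathrm{CPE} = \frac{1}{(i\omega)^n Q},$$

an ideal capacitor at $n = 1$ and a depressed (non-ideal) capacitance for
$n < 1$; fitted exponents here are typically 0.8–0.9. Throughout the
package $\omega = 2\pi f$ with $f$ in Hz — the convention of standard EIS
fitting software; stored data always carry $f$ in Hz. An R–CPE element can
be converted to an effective capacitance via

$$C = \left(R^{1-n} Q\right)^{1/n},$$

which reduces to $C = Q$ at $n = 1$ (`effective_capacitance()`). At low
biomass $R_\mathrm{dl}$ is poorly identifiable and its error contaminates
$C$; the calibration therefore uses the CPE coefficient $Q_\mathrm{dl}$
directly, which is precise in every regime.

```{r}
effective_capacitance(R_dl = 3.95e5, Q_dl = 2.14e-5, n_dl = 0.82)
```

## The CNLS estimator

`fit_circuit()` minimises the weighted sum of squared real and imaginary
residuals,

$$S(\theta)=\sum_k w_k\left[(\mathrm{Re}\,Z_k - \mathrm{Re}\,\hat Z_k)^2 +
(\mathrm{Im}\,Z_k - \mathrm{Im}\,\hat Z_k)^2\right],$$

with bounded Levenberg–Marquardt iterations on an analytic Jacobian.
Design choices that matter:

* **Weighting.** The default is modulus weighting, $w_k = 1/|Z_k|^2$. The
  media arc sits near $10^2\,\Omega$ while the double-layer branch reaches
  $10^5$–$10^6\,\Omega$; unweighted residuals would let the low-frequency
  tail swamp the media arc entirely. Unit and proportional
  (component-wise) weighting are selectable in `fit_config()`. Modulus
  weighting also makes the estimate scale-equivariant: scaling a spectrum
  by a constant scales the resistive/inductive parameters and inversely
  scales the capacitive ones, leaving relative estimates unchanged.
* **Parameterisation.** All parameters except $n_\mathrm{dl}$ are
  optimised in log space. The parameters span twelve orders of magnitude
  ($10^{-6}$ H against $10^6\,\Omega$), positivity is required, and
  relative steps are the natural moves for such scales.
* **Multi-start.** Five seeded starts (configurable): the heuristic
  initial guess plus four log-space perturbations of up to a factor 3.
  The best objective wins; ties go to the fit with the smaller
  $Q_\mathrm{dl}$ error estimate. A start that reaches an essentially
  exact fit short-circuits the rest.
* **Initial guess.** `initial_guess()` reads magnitudes off the spectrum:
  $R_\mathrm{offset}$ from $\mathrm{Re}\,Z$ at the top of the sweep,
  $L_\mathrm{setup}$ from the inductive $\mathrm{Im}\,Z$ there, the CPE
  exponent from the log–log slope of the low-frequency $-\mathrm{Im}\,Z$
  tail, and the CPE coefficient from $|Z|$ at the lowest frequency. For
  the full circuit the CPE and the total low-frequency offset are then
  refined by a quick simplified-circuit fit of the band below the media
  arc; the media shoulder height follows as the difference between that
  offset and the top-of-sweep offset. When that difference is swamped by
  the offset/exponent trade-off of the band fit, the guess falls back to
  a shoulder of 0.3 $R_\mathrm{offset}$ and a media time constant of
  about $10^{-3}$ s — the regime of a high-frequency shoulder for this
  cell geometry. Starts only need to be within a decade; the optimiser
  does the rest.

### Error estimates and goodness of fit

Per-parameter errors (`parameter_errors()`, the `nrmse_percent` field) are
percent relative standard errors from the curvature of the objective at
the optimum: with Jacobian $J$ of the weighted residuals and
$\hat\sigma^2 = S/(2N - p)$ for $N$ complex points and $p$ free
parameters, the covariance is $\hat\sigma^2 (J^\top J)^{-1}$; on
log-scale parameters the standard error is already relative. This
"percent error per parameter" is the quantity EIS fitting programs report
next to each estimate. `chi_squared` is $S/(2N - p)$ and
`sum_of_squares` is $S$; both depend on the weighting scheme, so they are
comparable across spectra fitted with the same configuration, not across
software packages. A rank-deficient linearisation yields `NA` error
entries rather than a crash.

### Model reduction at low biomass

At high biomass the low-frequency tail bends enough for
$R_\mathrm{dl}$ to be estimated (error estimates of a few percent); at
low biomass the CPE dominates to the bottom of the sweep and
$R_\mathrm{dl}$ is not accessible — its percent error grows by an order
of magnitude. `select_model()` fits the full circuit and falls back to
the simplified variant

$$Z = R_\mathrm{offset} + Z_\mathrm{CPE}$$

when the $R_\mathrm{dl}$ error exceeds `rdl_nrmse_threshold` (default
30 %, between the two regimes) or the full fit fails. Two details:

* The simplified circuit only describes the band below the media arc, so
  it is fitted to samples at or below `simplified_max_hz` (default
  10 Hz). There the media element is purely resistive and folds into the
  offset — which is exactly what the simplified circuit assumes. Fitting
  it to the whole sweep would push the media-arc misfit into the CPE and
  bias $Q_\mathrm{dl}$ by several percent; on the restricted band the
  bias is well under 1 %.
* $Q_\mathrm{dl}$ and $n_\mathrm{dl}$ are populated in every returned
  fit, so the calibration signal survives model reduction.

If $n_\mathrm{dl}$ converges to its upper bound 1.0 the element is simply
an ideal capacitor and the fit is reported as such; no refit is
attempted.

## Calibration to dry cell weight

`fit_dcw_calibration()` is ordinary least squares of $Q_\mathrm{dl}$ on
DCW. The line carries an intercept by default: cell-free media produce a
nonzero background signal, so forcing the line through the origin would
bias the slope (a through-origin option exists). Predictions invert the
line; negative estimates are clamped to zero with a warning, and
estimates outside the calibrated range (default 1–40 g/L, the range over
which the sensor was characterised) warn about extrapolation. Dry cell
weight and viable cell concentration are treated as equivalent — the
regime where dead cells are below a few percent — and a
`viability_fraction` scalar (default 1) lets callers with flow-cytometry
data correct for the dead fraction.

`fit_saturating_comparator()` fits the logarithmic response
$s = a\ln(\mathrm{dcw}) + b$ of an inline optical-density probe whose
linear range saturates at high biomass; it exists to demonstrate why the
impedance signal, which stays linear over the full range, is the better
online calibrand.

### Quality control

Flow-through measurements can produce Nyquist loops at low frequency:
$\mathrm{Re}\,Z$ falls back as the frequency decreases (negative
differential resistance), an electrode artifact rather than a property of
the suspension. `detect_negative_differential_resistance()` tracks, below
an onset frequency (default 10 Hz), the running maximum of
$\mathrm{Re}\,Z$ along the downward sweep and flags a spectrum when
$\mathrm{Re}\,Z$ drops below that maximum by more than 2 % of the local
$|Z|$. The comparison is cumulative rather than per-step: with ten points
per decade, a fold that is obvious in the Nyquist plane advances only a
fraction of a percent per step while the local $|Z|$ is dominated by the
imaginary part, so a per-step test at any noise-robust tolerance would
miss it. A passive circuit response has monotonically increasing
$\mathrm{Re}\,Z$ toward low frequency and is never flagged; flagged
spectra are dropped from calibration (the hardware-side remedy is a
higher excitation amplitude, so dropping, not modelling, is the right
software policy).

## The synthetic-data generator

Real cultivation spectra for this sensor are not publicly deposited, so
the generator defines the study conditions under which every stage is
tested:

* **Spectra.** `simulate_spectrum()` multiplies each model impedance by
  $1 + \varepsilon$, $\varepsilon$ complex Gaussian with standard
  deviation `relative_sigma` per component (default 1 %, a realistic
  relative accuracy for a dielectric analyzer in this band). An optional
  loop artifact collapses the sub-onset trace toward the origin to
  emulate the negative-differential-resistance loops.
* **Growth.** `biomass_trajectory()` is piecewise exponential: a batch
  phase (default $\mu = 0.55\,\mathrm{h^{-1}}$, 4 h, typical of
  *E. coli* on glucose) continuing continuously into a feed-controlled
  phase (default $\mu = 0.10\,\mathrm{h^{-1}}$, 15 h). The defaults span
  1 to about 40 g/L, the sensor's characterised range. Substrate, feed
  and induction dynamics are deliberately out of scope.
* **Biomass to parameters.** `params_for_biomass()` anchors the
  double-layer branch to the two reference fit rows: $Q_\mathrm{dl}$
  follows the true calibration line (slope $1.8\times10^{-7}$
  F s$^{n-1}$ per g/L — the resuspension-calibration slope — with the
  intercept set so $Q_\mathrm{dl}(1\,\mathrm{g/L}) = 1.62\times10^{-5}$;
  the reference value at 25 g/L, $2.14\times10^{-5}$, then agrees to
  within a few percent, the remainder being absorbed by the intercept);
  $\log_{10} R_\mathrm{dl}$ interpolates linearly in biomass between
  $4.44\times10^{6}\,\Omega$ at 1 g/L and $3.95\times10^{5}\,\Omega$ at
  25 g/L (a modelling convenience, not a mechanistic claim);
  $n_\mathrm{dl}$ interpolates 0.87 → 0.82 over the same anchors,
  clipped to $[0.75, 0.95]$. Setup and media elements are held at their
  high-biomass reference magnitudes — in reality they drift slowly with
  media composition, which the generator does not model.
* **Determinism.** Every stochastic operation takes an explicit seed;
  cultivation records derive per-record seeds from the run seed, so a
  scenario–seed pair reproduces a run exactly.

What passing tests on these data do show: the estimator recovers the
generating circuit essentially exactly on noiseless sweeps, keeps the
calibration parameter $Q_\mathrm{dl}$ within a fraction of a percent at
instrument-level noise, reproduces the identifiability contrast between
high and low biomass, and closes the loop from simulated monitoring data
to DCW predictions on the identity line. What they do not show: behaviour
under media drift, electrode fouling, temperature excursions, or the
late-fed-batch biomass overestimation seen in real monitoring runs, whose
mechanism is unknown and not emulated.

## Numerical choices and degenerate inputs

* Frequency grids are logarithmic, ten points per decade, 1 MHz → 0.1 Hz
  (71 points) by default — consistent with the degrees of freedom implied
  by the reference fits' quality ratio.
* Optimiser tolerances: `ftol` $10^{-12}$ on the objective, iteration cap
  100; fits that stop on the cap are flagged `converged = FALSE`, never
  raised as errors, and `select_model()` treats them as grounds for
  reduction.
* Spectra with no capacitive signature (flat resistors), sweeps narrower
  than three decades, and sub-8-sample spectra are rejected before
  fitting with informative errors.
* The effective-capacitance conversion guards $n < 0.05$, where the
  $1/n$ exponent would overflow.
* Parallel composition treats a non-finite branch as open and returns the
  other branch, so the simplified circuit is its own formula rather than
  a large-$R_\mathrm{dl}$ limit of the full one.

## Problem sizes

The shipped tests and the acceptance script use 71-point spectra; 50
random parameter draws (noiseless) plus 20 draws × 10–20 noise seeds for
the stochastic recovery statistics; and two simulated cultivations of 39
and 69 records for the end-to-end calibration experiment. These sizes
give stable medians while keeping a full run in the tens of seconds on a
single core.
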