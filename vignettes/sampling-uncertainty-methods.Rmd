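---
title: "Methods: Monte Carlo subsampling for plot-scale soil CO2 emission uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo subsampling for plot-scale soil CO2 emission uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxsample)
```

## The problem

Chamber measurements of soil respiration are point measurements: a PVC
collar samples a few hundred cm² of a plot that may span many km². Scaling
collar fluxes to a plot-mean emission therefore carries a spatial sampling
error that depends on how many collars were deployed and how heterogeneous
the plot is. `fluxsample` quantifies that error empirically — by resampling
the campaign itself — rather than through a parametric variance model, and
turns the resulting error-versus-sample-size curve into a concrete design
recommendation.

## The resampling estimator

Let the campaign provide one scalar per collar (mean temperature, mean
moisture, or seasonal emission): a population `A` of size `N`. For each
subsample size `k = 1 .. N−1`, `mc_cv_curve()` draws `M` subsamples without
replacement — each draw is a fresh uniformly random permutation of `1..N`
truncated to its first `k` indices — computes each subsample mean `E_i`,
and estimates

$$ CV_k \;=\; \frac{1}{E_N}\sqrt{\frac{1}{M-1}\sum_{i=1}^{M}\,(E_i-E_N)^2}\times 100\,\% $$

with `E_N` the full-sample mean. Three deliberate conventions:

* **Centring on `E_N`**, not on the mean of the `E_i`. Under sampling
  without replacement `E[E_i] = E_N`, so the two centrings agree to
  `O(1/M)`; we keep the full-sample mean because the quantity of interest
  is deviation *from the accepted plot value*.
* **Divisor `M−1`**, matching the usual sample-variance habit; at the
  default `M = 10,000` the difference from `M` is negligible but the
  convention is fixed so results are bit-reproducible.
* **Independent draws per `k`** (no permutation reuse across sizes) — the
  simplest independence structure. Duplicate subsamples across the `M`
  draws are allowed; for `M` finite they occur with small probability at
  realistic `N` and bias nothing.

Because the estimator is a plain function of SRSWOR subsample means, two
independent oracles exist and ship in the package:

* `exact_cv_enumeration()` enumerates all `choose(N, k)` subsets (guarded
  at 10⁶) and computes the `M → ∞` limit exactly;
* `closed_form_cv()` evaluates the survey-sampling identity
  $CV_k = \sqrt{(S^2/k)(1-k/N)}/E_N$, where `S²` is the `(N−1)`-divisor
  variance — the finite-population correction makes `CV_N = 0` and
  `CV_1` equal to the `N`-divisor population CV.

The two oracles agree to machine precision for every population (they are
the same quantity derived two ways), and the test suite holds the Monte
Carlo engine to within 3 % relative of both. This dual-oracle structure is
the backbone of the package's correctness argument.

## Optimal sample size

`optimal_sample_size()` discretises the CV curve's slope as the forward
difference `s_n = CV_{n+1} − CV_n` (% per collar) and declares
`n* = min { n : s_n > θ }` with threshold `θ = −1.0` by default: below the
threshold an added collar still removes more than one percentage point of
CV. The forward-difference convention is chosen because it makes the
detected `n*` satisfy the natural description "slopes below the threshold
strictly before `n*`, above it from `n*` on". Ties (`s_n = θ` exactly) do
not count as exceeding — the rule is a strict inequality. If every slope is
at or below the threshold the optimum is *not obtained*: the population is
too small for extra collars to stop paying, and the result flags that
rather than extrapolating. Note `n*` is monotone non-decreasing as the
threshold rises toward 0, which the tests verify on random curves.

The threshold's unit (% per collar) ties the rule to the axes of the CV
plot; it is a design convention, not a statistical optimum, and is exposed
as a parameter.

## Respiration models and seasonal integration

`resp_model()` fits `R = αe^{βT}`, `R = αW^β`, or `R = αT^βW^γ` per collar
by Levenberg–Marquardt nonlinear least squares *on the original scale*
(`minpack.lm`), with starting values from the closed-form log-linear
regression — exact for noiseless data, removing any seed dependence from a
smooth 2–3 parameter problem. Convergence uses a relative sum-of-squares
tolerance of 1e-10 and at most 500 iterations; non-convergence is an error
that carries the starting values and iteration count. `R²` is
`1 − SS_res/SS_tot` on the untransformed scale and may legitimately be
negative; constant `R` (zero `SS_tot`) is rejected as degenerate.
Preconditions mirror the formulas' domains: `R > 0` always (needed by the
log-scale start), `W > 0` for the power models, `T > 0` only for the
interactive model (the exponential model is happy with frost).
`average_r2()` summarises per-collar fits as mean ± SE with
SE = sd/√(number of collars), the conventional reading of a
"standard error over collars".

`integrate_emission()` drives the fitted model with the collar's continuous
half-hourly `T`/`W` record and integrates by the trapezoidal rule on a
regular 30-min grid spanning the window. Drivers — not fluxes — are
linearly interpolated across logger gaps, because drivers vary smoothly
while the flux is a nonlinear map of them; gaps longer than 24 h inside the
window are an error, as is a window outside the series span. Unit
conversions are exact constants: 10⁻⁶ mol/μmol, 12.011 g C and 44.01 g CO₂
per mol CO₂; both carbon-mass and CO₂-mass totals are reported since
conventions differ between studies. The default window is 16 June 00:00 to
19 September 24:00 (end-inclusive), the maize growing season at the
emulated site; it is a plain argument, and measurement campaigns that start
earlier simply pass their own dates.

`representative_window()` answers the survey-scheduling question: on the
mean diurnal cycle of a continuous respiration record, which times of day
sit within ±10 % (configurable) of the diurnal mean? Endpoints are reported
at the cadence of the record, runs touching both midnight edges are merged
into a single wrapped interval, and a constant record returns the whole
day. A record shorter than one full day is a coverage error.

## Error propagation

`propagate_error()` implements the total derivative of each model:
ΔR/R = βΔT (exponential — note the *absolute* ΔT, which is the correct
total derivative of `αe^{βT}` even though it is dimensionally unlike the
other two), ΔR/R = βΔW/W (power) and ΔR/R = βΔT/T + γΔW/W (interactive,
with terms added as if driver errors were independent). The inputs are
therefore split into an absolute `delta_T` and a relative `delta_W_rel`;
when driving the formulas from CV curves the mapping is
`delta_W_rel = CV_W/100` and `delta_T = (CV_T/100)·T̄` — a convention this
package states explicitly. `linearization_check()` compares the linear
formula against the exact prediction ratio; the discrepancy decays
quadratically in the perturbation, which the tests verify for all three
models — this is the internal consistency check of the propagation
formulas.

## The synthetic generator

`generate_campaign()` emulates the study system every stage is tested
against: an irrigated oasis maize plot, 5 × 5 km², 51 collars spread over
four quadrant subplots as (SW, SE, NE, NW) = (15, 15, 12, 9) — so the four
half-plot strips hold 30, 27, 24 and 21 collars — surveyed every 6 days
within an 8:30–12:00 window, with continuous half-hourly driver records
over a 16 June – 19 September season.

Heterogeneity is layered as follows, all parameters exposed in
`synthetic_config()`:

* **Across collars** (the spatial signal the CV curves measure): collar
  mean temperature, mean moisture and the respiration scale α are
  lognormal with CVs of 5 %, 10 % and 4 %. Lognormality guarantees
  positivity and makes the CV the natural parameter. Under the default
  interactive truth model (β = 1.649, γ = 0.622, central values of the
  plot-scale coefficient estimates) the emission CV compounds to
  √(cv_α² + (β·cv_T)² + (γ·cv_W)²) ≈ 11 %. The 5/10/11 ordering — stable
  temperature, irrigation-patterned moisture, emission compounding both —
  is the site pattern the pipeline-level tests check for.
* **Within collars**: temperature = collar mean + a 4 °C half-sine
  seasonal arc peaking mid-season + a 3 °C diurnal sine peaking
  mid-afternoon + white noise (0.5 °C); moisture = collar mean × a
  mean-one irrigation sawtooth (instant rise every 12 days, exponential
  decay to 43 % of the peak) × lognormal noise. Temperature is deliberately
  tame and moisture irrigation-dominated, as in arid farmland under river
  irrigation.
* **Observation noise**: chamber respiration is the truth model evaluated
  at the collar's instantaneous drivers times lognormal noise
  (σ = 0.1), so per-collar fits recover the generating exponents up to
  noise — a loop the tests close (median relative error < 2σ).
* α is centred so the plot-mean respiration at (20 °C, 25 %) equals the
  diurnal mean flux of 4.5 μmol m⁻² s⁻¹; the diurnal generator's peak
  default is 7.0 μmol m⁻² s⁻¹.

One survey time per date is drawn and shared by all collars; this keeps a
zero-noise, zero-CV configuration exactly degenerate (all collars
identical, all CVs 0, all `n* = 1`), a useful end-to-end sanity case.

What the generator does **not** emulate: spatial autocorrelation (collars
are drawn independently — consistent with the permutation-based resampling,
which ignores collar positions anyway), real irrigation scheduling,
rainfall, phenology-driven respiration trends, hysteresis or
photosynthesis-linked effects, and instrument drift. Passing tests
therefore demonstrate the *statistical machinery* on data with realistic
magnitudes and structure, not that any particular field site will show the
same optimal sample sizes.

## Numerical and testing choices

* The MC engine at `M = 10,000` has a CV-of-the-CV of roughly
  `1/√(2M) ≈ 0.7 %` relative, so the 3 % relative tolerance against the
  exact oracles leaves a ≈4σ margin without masking real defects.
* Coordinates are metadata (km from the plot's SW corner, quadrant labels
  validated against them); none of the statistics uses positions.
* Moisture is stored in volumetric percent and validated to [0, 100];
  fractional (0–1) water contents are rejected outright to avoid silent
  unit errors inside the power-law fits.
* Seeds: every stochastic function takes an explicit seed, restores the
  caller's RNG state, and records the seed in its result; orchestration
  derives distinct child seeds per stage. Identical seeds give
  byte-identical CSV outputs.
* Problem sizes in the test suite: oracle comparisons use 20 random
  populations of size 4–10 at `M = 10,000`; the site-pattern check runs 50
  full pipeline replicates (51 collars each) at `M = 2,000`; generator
  calibration checks use 30 seeds. These sizes keep the whole suite in the
  minutes range while leaving the statistical margins described above.

## Limitations

The CV curve conditions on the campaign actually collected: it measures
how well subsets reproduce the full-sample mean, not the (unknowable) true
plot mean, so `N` itself must be "large enough" for the analysis to be
informative — exactly the situation the not-obtained flag reports.
Model-based emission estimates inherit the empirical models' biases
(no hysteresis, no substrate effects), and the delta-method propagation is
first-order with independent errors; both are faithful to the design being
implemented rather than claims about soil carbon dynamics.
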