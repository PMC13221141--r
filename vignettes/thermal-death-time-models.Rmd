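---
title: "Thermal death time models: fitting and prediction under fluctuating temperatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal death time models: fitting and prediction under fluctuating temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdtsurv)
```

## The problem

Ectotherms held at a constant stressful temperature fail — are knocked down,
enter coma, or die — after a time $t_f$ that shortens roughly exponentially
as temperature rises. On the log scale this is the classical thermal death
time (TDT) relation

$$\log t_{50}(T) = \beta_0 + \beta_1 T,$$

with $\beta_1$ typically strongly negative within the stressful range (for
the fly knockdown regime emulated by this package's simulator, about
$-0.9\,^\circ\mathrm{C}^{-1}$ on the natural-log scale: medians fall from
hours at 33 °C to about a minute at 40 °C). The TDT line predicts *median*
failure times, but many questions — survival probabilities under a heat
wave, population persistence — need the whole distribution of failure
times, and need it under *fluctuating* temperatures.

## The survival model

`tdtsurv` models failure times at one temperature as log-logistic:

$$S(t) = \left(1 + (t/a)^k\right)^{-1},$$

where the scale $a$ (minutes) equals the median failure time and the shape
$k > 0$ controls the spread:

$$\operatorname{var}[\log t_f] = \frac{\pi^2}{3k^2}.$$

Small $k$ means a flat, gradually declining survival curve with a long
right tail of failure times; large $k$ approaches a switch-like
(deterministic) failure at $t = a$. Because the variance of $\log t_f$ is
scale-free, temperature effects on the *spread* of failure times are
separate from the TDT trend in the *median* — and in the knockdown data
this package is designed for, the spread grows with temperature, so an
"average" survival-curve shape shared across temperatures is not a safe
assumption.

A note on the hazard: we implement $h(t) = f(t)/S(t)$ in the form implied
directly by $S(t)$ above,

$$h(t) = \frac{(k/a)(t/a)^{k-1}}{1 + (t/a)^k},$$

which rises to a single mode and then declines when $k > 1$ and declines
monotonically when $k \le 1$. Alternative printed forms of the log-logistic
hazard circulate in the literature with the scale folded in
inconsistently; `llogis_hazard()` is defined so that the identity
$h = f/S$ holds to machine precision against `llogis_density()` and
`llogis_survival()`, and the tests enforce it.

## Fitting to constant-temperature assays

`fit_cell()` estimates $(a, k)$ for one species × temperature cell by
maximum likelihood; `fit_aft_model()` fits all records jointly as an
accelerated failure time model with

$$\log a(T) = \beta_0 + \beta_1 T, \qquad
  \log k(T) = \gamma_0 + \gamma_1 T,$$

the second link optional (`shape_link = "constant"` fixes $\gamma_1 = 0$).
The log link on the shape guarantees $k > 0$ everywhere. A shape that
"declines linearly" with temperature could equally be modeled on the
identity scale, but the identity link can cross zero under extrapolation;
it is available via `shape_transform = "identity"` for sensitivity
analysis, and in the narrow stressful range the two are close.

Numerical choices that matter:

* Optimization is quasi-Newton (BFGS) on unconstrained coordinates with a
  relative objective tolerance of 1e-10 and multi-start: a moment/OLS-based
  start, ±0.2 perturbations, ±0.1 perturbations of the shape slope, plus
  any caller-supplied starts.
* The temperature covariate is centered internally before optimization.
  On the raw Celsius scale the intercept and slope are nearly collinear
  (temperatures cluster near 37), which degrades quasi-Newton search
  badly enough to corrupt likelihood-ratio statistics. Estimates and
  covariance are mapped back, so the reported coefficients are in plain
  °C with no recentering.
* Starting values: scale from the sample median; shape from inverting
  $\operatorname{var}[\log t_f] = \pi^2/(3k^2)$ on the residual variance
  of log times.
* Standard errors come from the observed information at the optimum; a
  fit whose Hessian is not positive definite is flagged, never silently
  accepted.
* Degenerate cells (all failure times identical, shape $\to \infty$) are
  an error, and `filter_min_trial_size()` removes assay groups below 10
  individuals by default — small trials make shape estimates unstable and
  can prevent convergence.

`rank_families_by_aic()` compares the log-logistic against exponential,
Weibull, log-normal and Gompertz fits (location linear in temperature,
shape constant), ranking by AIC with ties (within 1e-9) broken by fewer
parameters, then family name. The exponential — a constant hazard, the
"failure rate depends only on current temperature" assumption — is the
natural straw man and loses badly whenever failure times are unimodal
around the median. The Gompertz is parameterized as hazard
$h(t) = \text{rate} \cdot e^{\text{shape}\, t}$ (conventions differ across
sources; this matches `flexsurv`).

Two diagnostics probe the TDT assumptions. `test_shape_trend()` is a
likelihood-ratio test of $\gamma_1 = 0$ (df = 1); with several species,
`pooling = "pooled"` gives each species its own location and shape
intercepts but shares $\beta_1$ and $\gamma_1$ — a fixed-effect
simplification of a multi-species trend test, chosen because a full
random-effects construction is outside this package's scope. The full fit
always includes the reduced solution among its starts, so the nested
likelihood ordering holds by construction. `test_ph_nonconstancy()` checks
the proportional-hazards alternative by adding a temperature × log(time)
time-varying coefficient to a Cox model (df = 1): when shape changes with
temperature, hazard ratios between temperatures cannot be constant in
time, and a PH treatment of knockdown data is invalid.

## Predicting under fluctuating temperatures

Three predictors consume a `temperature_profile()` (stepwise by default —
experimental profiles are chamber setpoints — or linearly interpolated,
holding the final temperature beyond the last knot):

1. **Additive damage** (`predict_median_jorgensen()`): injury accrues at
   rate $1/t_{50}(T)$ and the median failure occurs when
   $D(t) = \int_0^t \mathrm{d}u / t_{50}(T(u))$ reaches 1. Deterministic;
   for stepwise profiles the integral and its inversion are closed-form.
2. **Average survival curve** (`build_average_relative_curve()` +
   `predict_survival_rezende()`): every observed static failure time is
   rescaled to relative time $r = t_f / t_{50}(T_\text{assay})$, pooled
   across temperatures into a single empirical survival curve, which is
   then evaluated at the accumulated relative time $R(t)$. The working
   curve interpolates linearly between the midpoints of the empirical
   jumps; the raw step function is also exposed
   (`empirical_survival()`). The relative density is a kernel estimate on
   $\log r$ (Silverman's rule bandwidth, adjustable) transformed back.
3. **Increasing variance** (`predict_survival_increasing_variance()`):
   the parametric model with temperature-linked scale *and* shape,
   $$S(t) = \left(1 + D_a(t)^{\,k(T(t))}\right)^{-1}, \qquad
     D_a(t) = \int_0^t \frac{\mathrm{d}u}{a(T(u))},$$
   with the shape evaluated at the instantaneous temperature. At constant
   temperature this reduces *exactly* to the static log-logistic — the
   binding design requirement. Where the shape changes mid-profile the
   dynamic construction is genuinely a modeling choice; alternatives
   (duration-weighted mean shape, shape frozen at the dominant
   temperature) are selectable via `shape_eval` and the choice is
   recorded in every prediction object.

Medians are found by bisection to 1e-6 min inside a grid bracket; the
search horizon defaults to 10× the constant-temperature median at the
profile's coolest temperature, and predictions that never reach $S = 0.5$
within the horizon are flagged, never silently truncated. Densities on the
output grid (default step 0.1 min; refining below this changes survival
curves by under 1e-4) come from central finite differences of $S$,
clipped at 0. `profile_log_likelihood()` scores observed failure times
against a predicted curve with the density floored at 1e-12 per minute
(the floor count is reported), so a few observations in a numerically
empty tail cannot produce an infinite criterion. Temperatures beyond the
fitted range extrapolate the log-linear links and trigger a warning.

`run_full_comparison()` chains everything: TDT regression, pooled curve,
joint AFT fit, per-set predictions under all three models, sums of
absolute median errors, per-set log-likelihood differences
(increasing-variance minus average-curve; positive favors the former), a
two-sided paired t test on those differences, and the count of sets
favoring the increasing-variance model. When sets carry a sex label the
sexes are fitted and scored separately by default (`pool_sexes = TRUE`
pools them); observed medians use the standard mid-point convention.

## The synthetic-data generator

`generate_static_dataset()` draws log-logistic failure times from the
temperature links above. Its defaults are the study conditions the rest of
the package is tested under: temperatures 33–40 °C in 1 °C steps, 20
individuals per cell (matching the 10–30 per-cell regime of real
knockdown assays), $\beta_0 = 35.6$, $\beta_1 = -0.9$ (medians ≈ 6 h at
33 °C down to < 1 min at 40 °C), $\gamma_0 = 4.7$, $\gamma_1 = -0.1$
(shapes declining from ≈ 4 to ≈ 2, i.e., variance of log failure time
increasing with temperature, with high-temperature shapes in the 1–3
range typical of flies). `generate_temperature_profile()` builds constant,
step, ramp and sinusoid profiles bounded to 34–42 °C, and
`sample_under_profile()` inverse-CDF samples from the predicted dynamic
curve. Sub-seeds for each cell and set derive from the root seed by a
fixed counter scheme keyed on the temperature (or set index), so adding a
cell never changes another cell's draws.

What the generator does *not* emulate — and therefore what passing tests
on synthetic data cannot show about real assays: acclimation and
hardening during the assay, recovery at permissive temperatures,
order-dependent (non-additive) damage, individual frailty heterogeneity
beyond the log-logistic spread, measurement discreteness of observation
intervals, and between-trial batch effects. Real fluctuating-temperature
data are known to violate strict additivity (observed medians exceed
additive-damage predictions when cooler-but-stressful temperatures
dominate), so agreement between the three predictors on synthetic data is
a consistency check, not evidence about organisms.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` size their simulations as
follows, balancing Monte-Carlo resolution against desk-scale runtimes:
1e6 draws for the variance-identity oracle (the 1% band is then > 5
Monte-Carlo standard errors wide); 100 replicates of 5 temperatures × 200
individuals for coefficient recovery within 3 standard errors; 500 null
replicates of 5 × 50 for the size of the shape-trend LR test (50 per cell
is the smallest size at which the finite-sample rejection rate matched
the asymptotic chi-square reference in calibration runs; 30 per cell
over-rejects at ≈ 0.08); 1e4 draws for the dynamic sampling
sup-norm check at 0.02; and 10 synthetic assay sets of 15 individuals for
the end-to-end three-model comparison.

## Known limitations

* Likelihood fitting assumes fully observed failure times; right
  censoring is not handled (knockdown assays observe every individual),
  and interval censoring is out of scope.
* The multi-species trend test uses fixed species intercepts, not random
  effects; with many species and few cells each, its df = 1 statistic is
  an approximation.
* The average-curve model inherits the noisiness of small pooled samples;
  with few individuals its kernel density can be rough, and the package
  deliberately does not smooth the survival curve beyond jump-midpoint
  interpolation.
* Dynamic-shape evaluation at the instantaneous temperature is one of
  several defensible constructions; results for strongly fluctuating
  profiles with large shape gradients should be checked against the
  `shape_eval` alternatives.
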