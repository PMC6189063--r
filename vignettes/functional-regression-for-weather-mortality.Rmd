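---
title: "Functional regression models for temperature-related mortality"
author: "fdamort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional regression models for temperature-related mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdamort)
```

## The models

Environmental epidemiology usually relates daily death counts to scalar
summaries of temperature (the daily mean, minimum or maximum), possibly
with lagged effects. `fdamort` instead treats temperature as *functional
data* — whole curves are the unit of observation — and implements two
functional regression models for cardiovascular-mortality applications,
together with the classical models they are compared against.

**Scalar-response functional linear model (SFLM).** For summer day $i$
with death count $y_i$ and previous-day temperature curve
$x_{i-1}(s)$, $s \in [0, 24]$ hours,

$$\ln(y_i) = s(i) + \beta_0 + \int_0^{24} x_{i-1}(s)\,\beta_1(s)\,ds
  + \epsilon_i .$$

Here $s(i)$ is a long-term-trend natural spline with one interior knot
every three months of observed data, and $\beta_1(s)$ — the object of
interest — gives the effect of each hour of the previous day on today's
log mortality. Counts enter as $\ln\max(y_i, 0.5)$: at a baseline of
about 17 deaths/day zero counts are vanishingly rare, and the guard keeps
the model a Gaussian regression on the log scale rather than switching to
a Poisson likelihood (`lag_gam()` and `dlnm()` make the same choice so
that all models compete on the same footing).

**Historical fully functional linear model (FFLM).** For year $i$ with
log mortality-rate curve $y_i(t)$ and same-year temperature curve
$x_i(s)$, $s, t \in [0, 365]$ days,

$$\ln(y_i(t)) = s(i) + \beta_0(t)
  + \int_{t-60}^{t} x_i(s)\,\beta_1(s,t)\,ds + \epsilon_i(t),$$

where $s(i)$ is now a smooth trend in the year index (at most 4 df),
$\beta_0(t)$ a functional intercept carrying the seasonal mortality
profile, and $\beta_1(s,t)$ a coefficient surface constrained to the
*historical band* $t - 60 \le s \le t$: only the preceding 60 days of
temperature may act on day $t$. The 60-day maximum lag follows the
longest lag effects reported for daily mean temperature.

## Functional data construction

Curves are built from discrete measurements by unpenalized least-squares
spline smoothing: cubic B-splines (order 4) with *equally spaced*
interior knots, the knot count selectable by leave-one-out
cross-validation (`select_knots_loocv()`). Point-level LOO is computed
with the hat-matrix identity $e_{(l)} = e_l / (1 - h_{ll})$, summed over
curves, which equals brute-force refitting exactly; ties are broken
toward fewer knots. Smoothness is thus controlled by the knot count
alone — there is no additional roughness penalty at the smoothing stage,
which keeps the construction literal and leaves penalization to the
regression stage where it is identifiable.

Defaults for the annual application: temperature curves on a
dimension-40 basis (a knot roughly every 9 days — the curves track the
measurements closely, as daily temperature is already smooth), mortality
rate curves on a dimension-16 basis (a knot every ~23 days — day-to-day
count variation is Poisson noise around a slowly varying rate, so the
smoother is deliberately coarse; `log_rate_curves()` clips the rate at
0.1 deaths/day before logging so the log is always defined). Daily
exposure curves for the SFLM use a dimension-12 basis on $[0, 24]$.

All integrals — Gram matrices, cross-Gram matrices implementing
$\int x\,\beta_1$, roughness penalties, and the windowed historical
integrals — use Gauss–Legendre quadrature per knot span with
order + 1 nodes. Products of B-splines are piecewise polynomials, so
these integrals are polynomial-exact: quadrature is never a tolerance
source, and the test suite checks every such construction against dense
Riemann oracles at $10^{-6}$ relative error.

## Estimation

Both functional models are estimated by penalized least squares with
second-derivative roughness penalties (on $\beta_1(s)$ for the SFLM;
anisotropic in $s$ and $t$ for the FFLM surface), the weights chosen by
generalized cross-validation over a logarithmic grid that is rescaled by
$\mathrm{tr}(X'X)/\mathrm{tr}(P)$ per block so the grid is dimensionless.

Two estimation choices deserve comment.

* **Band support is structural.** The FFLM surface is a tensor-product
  B-spline expansion in which coefficients of basis pairs whose support
  does not intersect the historical band are exactly zero, and
  evaluation multiplies by the band indicator, so
  $\beta_1(s, t) \equiv 0$ off the band — exactly, not approximately.
  For $t < 60$ the integral is truncated at day 0 rather than importing
  the previous year's temperature.

* **Effective sample size in the FFLM's GCV.** The response curves are
  discretized on a 365-point grid, giving $31 \times 365 = 11{,}315$
  regression rows, but the smoothed response only carries
  $31 \times 16 = 496$ free coordinates. Feeding the raw row count into
  GCV makes its denominator insensitive to the penalty and the criterion
  degenerates to the residual sum of squares, i.e. almost no smoothing.
  `fflm()` therefore evaluates GCV with the effective sample size
  $n_\mathrm{years} \times \dim(\text{mortality basis})$. In surface
  recovery simulations this is the difference between correlations of
  about 0.86 and about 0.97 with the generating surface.

* **Identifiability.** Temperature curves are centred at their
  across-year mean curve before entering the FFLM, so the surface acts
  on temperature *anomalies* and the seasonal temperature cycle cannot
  be traded against $\beta_0(t)$.

## Wild bootstrap confidence bands

Functional regression lacks convenient asymptotic theory for pointwise
intervals, so `wild_bootstrap_band()` uses the wild bootstrap:
$y^*_i = \hat y_i + v_i\,\tilde e_i$ with i.i.d. Rademacher signs $v_i$
(the simplest valid multiplier law), refitting with the smoothing
parameter frozen at the original fit's value, and taking pointwise
2.5%/97.5% percentiles over 500 replicates by default. Multiplying
residuals by signs rather than permuting them preserves
heteroscedasticity. Two small corrections matter in practice:

* residuals are leverage-corrected, $\tilde e_i = e_i / \sqrt{1 -
  h_{ii}}$, undoing the variance deflation of fitted residuals;
* because the refit is penalized, the replicate distribution is centred
  on the *noiseless refit* of the fitted values and its deviations are
  re-anchored at the point estimate; otherwise every replicate is
  double-shrunk and the band is biased toward zero. With zero residuals
  the band then collapses exactly onto the estimate, as it should.

In the recovery scenario below (500 days, known sinusoidal
$\beta_1$), 200 simulations of 200 replicates give average pointwise
coverage close to, slightly below, the nominal 95% — the residual gap is
the familiar smoothing-bias problem of nonparametric intervals, not a
bootstrap failure.

## Classical baselines

For the daily application, `lag_gam()` regresses log counts on the same
trend spline plus a penalized cubic regression spline (10 basis
functions, GCV) in one lag-1 scalar summary — minimum, mean, maximum or
diurnal range, computed by `summarize_day()`, which flags days with
fewer than 18 of 24 readings instead of silently summarizing them. The
smooths are fitted with `mgcv`.

For the annual application, `build_crossbasis()` constructs the
distributed-lag cross-basis: cubic B-splines over temperature with
interior knots at the 10th/75th/90th percentiles of the observed series,
and over lag $[0, 60]$ with interior knots equally spaced on the
$\log(\mathrm{lag}+1)$ scale (so lag 0 is included), combined as
lag-summed tensor products. `dlnm()` fits these columns ridge-penalized
(GCV), optionally interacting them with one day-of-year harmonic so the
exposure–lag response may vary over the season. One design choice is
deliberate: the DLNM's seasonal control is carried by day-of-year
harmonics shared across years plus a slow trend (one knot per year of
data), *not* by a flexible calendar-time spline. A 91-day-knot calendar
spline absorbs each year's seasonal cycle in-sample but cannot predict a
held-out year — in leave-one-year-out CV it produces RMSEs around 10
deaths/day, worse than predicting the mean — whereas season terms that
transfer across years put the DLNM on the competitive footing it has in
the literature.

## Model comparison

`blocked_cv_rmse()` implements blocked leave-one-year-out
cross-validation: each calendar year is one fold, the model is refitted
without it, and the held-out year is predicted on the count scale
(functional predictions are discretized to daily values first). Held-out
squared errors are pooled across folds before the square root, giving
one global RMSE per model; per-fold RMSEs are reported for diagnostics.
Two scoring details: trend splines are frozen at their boundary value
when an edge year must be predicted (no long-range trend extrapolation),
and days without a full 60-day lag history (the first 60 days of the
whole series, DLNM only) are not scored.

## The synthetic data generator

The study's administrative mortality and weather data are not
redistributable, so `mort_scenario()` defines a seeded generator that
emulates their statistical structure and makes every stage testable:

* temperature = annual sinusoid (mean 6.5 °C, amplitude 15 °C, peak near
  day 205) + (hourly mode) diurnal sinusoid (amplitude 4 °C, peak 15 h)
  + AR(1) noise (hourly mode: coefficient 0.97, innovation SD 0.6 °C;
  daily mode: 0.75 and 2.6 °C, giving realistic ~4 °C daily anomalies);
* counts are Poisson draws (optionally gamma-mixed) from a log-rate =
  baseline $\ln 17$ + slow linear trend + (annual mode) a winter-excess
  seasonal cycle of amplitude 0.15 + the functional term with a *known*
  coefficient.

The default known coefficients are a quarter-amplitude sinusoid
$0.25\sin(2\pi s/24)/24$ for the daily mode and a smooth, mostly
negative banded surface whose strength varies over the season for the
annual mode, its amplitude set so the historical term has SD ≈ 0.1 on
the log scale. These defaults were calibrated once, to the published
descriptive scale of the application — daily counts with mean 17 and SD
≈ 5 — and left alone; at those values the generator reproduces that
scale almost exactly (mean ≈ 17.2, SD ≈ 5.0).

What the generator does *not* emulate: weather is a single homogeneous
series (no spatial structure, no humidity or pollution covariates);
temperature noise is Gaussian AR(1) rather than the skewed,
regime-switching noise of real weather; mortality has no day-of-week
effects, epidemics or heat-wave harvesting dynamics. Passing recovery
tests therefore demonstrates that the estimators recover what they model
on data satisfying their assumptions — not that real city-scale
registry data would yield these particular surfaces.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use the study-scale sizes
throughout: 460 summer days (five June–August seasons) or 500 days for
recovery runs; 31 years × 365 days for the annual application; 500
bootstrap replicates as the default band; 200 simulations × 200
replicates for the coverage study; 10 seeds for the CV-ranking check.
All randomness flows from explicit integer seeds, and identical seeds
give byte-identical simulations, fits, bands and CV tables.

## Known limitations

* Both functional fits are Gaussian on log counts; a Poisson or
  quasi-Poisson likelihood would be more faithful at low rates.
* Bands are pointwise percentile bands, not simultaneous; they slightly
  undercover at sharp curvature of the target (smoothing bias).
* The FFLM reports no uncertainty for the surface.
* Exposure curves span a single day (SFLM) or year (FFLM); multi-day
  exposure windows and nonlinear functional terms are out of scope.
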