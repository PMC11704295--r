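---
title: "Methods: two-stage heat-mortality projection with a COVID-19 benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage heat-mortality projection with a COVID-19 benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`heatmort` implements the standard two-stage design of environmental
time-series epidemiology and carries it through to projections at global
warming levels (GWLs).

**Stage one.** For each location, daily death counts $Y_t$ are modelled by a
quasi-Poisson regression with log link,

$$\log E[Y_t] = \alpha + \mathbf{cb}_t^\top \boldsymbol\eta
  + s(t;\, 8\,\mathrm{df/year}) + \gamma_{\mathrm{dow}(t)},$$

where $\mathbf{cb}_t$ is the DLNM cross-basis of daily mean temperature — a
natural cubic spline of temperature (internal knots at the 10th, 75th and
90th percentiles of the observed series, boundary knots at its range, no
intercept; dimension $v_x = 4$) crossed with a natural cubic spline of lag
over 0–21 days (three internal knots, intercept; dimension $v_l = 5$, so 20
cross-basis terms). The time spline $s(t)$ absorbs seasonality and long-term
trends; day-of-week indicators capture the weekly cycle. Overdispersion
$\phi$ is estimated from the Pearson statistic and scales all standard
errors by $\sqrt\phi$.

The fitted exposure–lag–response surface is reduced to the one-dimensional
*cumulative* exposure–response by summing the lag basis:
$\boldsymbol\beta = (I_{v_x} \otimes \mathbf{s})^\top \boldsymbol\eta$ with
$\mathbf{s} = \sum_{\ell=0}^{21} B_\ell$, the same linear map propagating the
covariance. The minimum mortality temperature (MMT) — the argmin of the
cumulative log relative risk — becomes the reference at which
$\log \mathrm{RR} = 0$.

**Stage two.** Reduced coefficient vectors are pooled across locations in a
multivariate random-effects meta-regression
$\boldsymbol\beta_i \sim N(\Theta^\top x_i,\, \Psi + V_i)$ estimated by REML
($\Psi$ through its Cholesky factor, fixed effects profiled out by GLS, BFGS
on the profiled objective). Best linear unbiased predictions shrink each
location toward the pooled prediction,
$\boldsymbol\beta_i^{\mathrm{blup}} = \Theta^\top x_i +
\Psi(\Psi + V_i)^{-1}(\boldsymbol\beta_i - \Theta^\top x_i)$, with
covariance accounting for fixed-effect uncertainty; the MMT is re-found on
each BLUP curve.

**Climate preparation.** Each climate model's annual global-mean anomaly
(relative to 1850–1900) defines its GWL windows: the 20-year period centred
on the first year at which the centred 20-year running mean reaches the
level (+1, +1.5, +2, +3 °C by default), so models with different climate
sensitivities realise a level in different decades. Daily model temperatures
at the location are bias-corrected by empirical quantile mapping against the
station record (99 quantile pairs, one map per calendar month, linear
interpolation between fitted quantiles, constant offset beyond them).

**Projection.** For every day of a bias-corrected window with temperature
above the MMT, the attributable fraction is
$\mathrm{AF}_t = (\mathrm{RR}_t - 1)/\mathrm{RR}_t$; attributable deaths are
annualised over the 20-year window and divided by total deaths
($365.25 \times$ baseline) to give the annual heat-mortality fraction $h$.
Beyond the observed temperature range the cumulative curve continues
log-linearly (the natural spline is linear past its boundary knots, so the
continuation is continuous with continuous first derivative). Uncertainty
comes from Monte-Carlo simulation: 1000 draws (by default) from
$N(\boldsymbol\beta^{\mathrm{blup}}, V^{\mathrm{blup}})$, MMT re-found per
draw, $h$ recomputed for each draw under each model's window, and all
draw-by-model values pooled into one empirical distribution whose 2.5th /
50th / 97.5th percentiles form the empirical confidence interval. This pools
coefficient and across-model climate uncertainty into a single distribution
rather than nesting summaries.

**Comparison metric.** A country's COVID-19 mortality fraction $c$ is the
ratio of its COVID-19 deaths (whichever of 2020 or 2021 was worse) to total
deaths implied by the crude death rate (per 1000) and population. The
headline metric is $Y = c/h$: the number of years over which cumulative
heat-attributable deaths equal one year of COVID-19 deaths. The *best* case
maps to the lower eCI bound of $h$ (fewest heat deaths, most years), the
*average* case to the median, the *worst* case to the upper bound. $Y$ is
reported unrounded; any rounding to whole years is a rendering decision
(round half up).

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| exposure knots | 10, 75, 90 | percentiles | standard placement for mean-temperature curves |
| lag window | 21 | days | captures delayed heat effects and harvesting |
| lag knots | 3, log-spaced | lag scale | `lag_knot_scale = "linear"` gives equal spacing |
| time spline | 8 | df/year | `df_per_year` in `heat_dlnm()`; years counted as days/365.25 |
| MMT search | 1st–99th pct, 0.1 °C grid | — | avoids boundary artefacts; ties broken toward the median |
| GWL levels | 1, 1.5, 2, 3 | °C | per-model centred 20-year windows |
| quantile map | 99 quantiles, monthly | — | `by_month = FALSE` for a single annual map |
| Monte-Carlo draws | 1000 | — | `n_sim`; acceptance-scale runs use 200 |

## The synthetic-data generator

No real mortality or climate archive is redistributable, so every input is
emulated with known ground truth:

* **Temperatures**: seasonal sinusoid (annual mean 15 °C, amplitude 8 °C,
  peak mid-July) plus AR(1) noise (stationary sd 3 °C, lag-1 correlation
  0.7) — the persistence matters because the DLNM convolves 22 days of lags.
* **Deaths**: negative binomial with the configured variance/mean ratio
  (1.3 by default; quasi-Poisson has no generative form, and the negative
  binomial preserves the mean model the estimator assumes), log-mean built
  from a known U-shaped cumulative log-RR curve distributed over the lags by
  *normalised* geometric weights — because the weights sum to one, the true
  cumulative curve equals the configured curve exactly, which is what makes
  end-to-end recovery checkable. The default curve reaches RR 1.42 ten
  degrees above the MMT (19 °C) and RR 1.11 ten degrees below: heat steep,
  cold flat, as in large-city analyses. Records span 29 calendar years
  ending in 2019, the length of the observational period the pipeline
  emulates; scaled test fixtures use 2–10 years.
* **Heterogeneity**: log-normal multipliers (sd 0.15) on the heat/cold
  coefficients and a normal shift (sd 1.5 °C) on each location's MMT.
* **Climate models**: the same station generator with an independent noise
  stream, plus a constant per-model bias (mean +1, sd 1.5 °C) and a linear
  warming trend; per-model warming rates spread log-normally (sd 0.1) around
  0.3 °C/decade so GWL windows genuinely differ by model. The global-mean
  anomaly track passes 0.6 °C in 2000 and rises at the model's rate;
  interannual anomaly noise is off by default so closed-form crossing-year
  checks hold.
* **COVID-19 table**: one country per location; populations log-normal
  around 5 million, crude death rates 6–11 per 1000, COVID-19 deaths 2–25%
  of implied total deaths in each year.

Sub-streams (location temperature, counts, heterogeneity, model bias, etc.)
derive from the master seed by a fixed counter scheme, so adding a model or
location never perturbs previously generated series, and identical
configurations are bit-identical.

What the generator does **not** emulate: spatially structured climate
(every location shares one climate), meta-predictors with real explanatory
power (region, climate class and GDP are decorative labels, so pooling
tests use intercept-only meta-regression), reporting artefacts (weekday
undercounts, holidays), demographic change, and non-stationary variance in
the climate models. Passing tests therefore demonstrate correctness of the
estimation machinery under a faithful data-generating model, not robustness
to everything real surveillance data does.

## Numerical choices

* First-stage IRLS: `glm` with deviance tolerance 1e-8, 100 iterations max;
  non-convergence and all-zero or negative counts are errors, as is a
  rank-deficient cross-basis.
* Rows whose 21-day lag window is incomplete (series start) or overlaps a
  missing day are dropped from the likelihood rather than padded — padding
  would fabricate exposure history.
* REML: $\Psi$ initialised at $0.1 \times \overline{V_i}$, log-diagonal
  Cholesky parameterisation, BFGS with relative tolerance 1e-10; singular
  designs are reported with the offending columns.
* MMT: 0.1 °C grid; exact ties resolved toward the median observed
  temperature; re-found per Monte-Carlo draw (coherent with coefficient
  uncertainty; a fixed-MMT variant would understate it).
* Attributable fractions are floored at zero: an individual Monte-Carlo
  draw can dip marginally below RR = 1 between grid points, and negative
  attributable deaths have no interpretation here.
* Quantile maps use type-1 (inverse-ECDF) quantiles, which makes the
  calibration closure exact: corrected calibration-period model quantiles
  reproduce station quantiles to machine precision at the fitted
  probabilities.
* Nearest-grid-cell ties are broken by (lat, lon) lexicographic order;
  equality is assessed with a 1 m slack on the great-circle distance.
* Pipeline CSVs are written with 10 significant digits so identical
  configurations rerun byte-identically.

## Design choices where the method is genuinely open

* **Lag-knot placement.** "Equally distributed" lag knots admit two
  readings; the cited DLNM software convention is equal spacing on the
  log-lag scale, which concentrates flexibility at short lags where the
  acute heat response lives. Log spacing is the default; linear spacing is a
  flag.
* **GWL window variant.** Windows are centred on the crossing year of the
  centred 20-year running mean; a first-crossing-start variant is available.
* **Monthly quantile maps.** Bias in climate models is seasonal; monthly
  maps correct it at the cost of 12× fewer calibration points per map. With
  at least a decade of overlap each monthly map still rests on ~300 days.
* **Pooled eCIs.** Draw × model values are pooled into one empirical
  distribution (1000 × M values) rather than summarising per-model medians
  first; the pooled form treats coefficient and climate-model uncertainty as
  one uncertainty budget.
* **Projection baseline.** Daily baseline deaths are held at the
  observed-period mean: no adaptation or population change is modelled, so
  projections isolate the climate signal.
* **Interfaces.** The package's users work in R, so the orchestration layer
  is `run_pipeline()` over a declarative `run_config()` (YAML-readable),
  with a thin command-line wrapper in `inst/scripts/heatmort` for shell use.

## Verification scale and known limitations

The test suite verifies construction against brute-force oracles (cross
basis, reduction, GWL scans), closed forms (shrinkage factors, AF
arithmetic, the 20-year worked example) and recovery simulations. Problem
sizes are chosen to be decisive yet quick: parameter recovery uses a
10-location × 10-year study for CI coverage plus 100 single-location
replicates for MMT error; end-to-end recovery uses 21 replicate studies of
3 locations × 3 models at full 29-year records with 200 Monte-Carlo draws.

Known limitations, visible in those checks:

* **MMT identifiability.** With the default flat cold flank, the cumulative
  curve's minimum is weakly identified; single-location MMT estimates
  scatter with a median error around 1.2–1.5 °C and a cold-ward displacement
  (the minimum of a noisy curve falls below the true minimum). A sharp
  symmetric curve recovers the MMT to ~0.5 °C with no bias — the estimator
  is sound; the spread is a property of flat curves, and it propagates into
  mild upward noise in the heat fraction near the MMT.
* **Extrapolation.** Log-linear continuation understates a truly quadratic
  log-RR beyond the observed range; the discrepancy grows with warming level
  but remains small relative to tail-estimation noise at these scales.
* **Single-run noise.** A 3-location study estimates the warm-tail slope
  from a few dozen hot days per location; single-run heat-fraction errors of
  ±15% are normal, which is why recovery is judged on medians over
  replicate studies.
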