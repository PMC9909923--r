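---
title: "Methods: distributed-lag case-crossover analysis of temperature-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed-lag case-crossover analysis of temperature-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlnmcc)
```

# The scientific problem

Short-term exposure to both unusually cold and unusually hot weather raises
the risk of cardiovascular death, with effects that unfold over days to
weeks: cold effects tend to appear almost immediately and decay, while heat
effects are often delayed and can be followed by mortality displacement
("harvesting"). `dlnmcc` implements the full analysis chain used to quantify
this burden in a tropical, individual-level mortality setting: it constructs
a physiologically weighted exposure (apparent temperature), models the
exposure–lag–response surface with a distributed lag non-linear model (DLNM)
fitted under a time-stratified case-crossover design, locates the minimum
mortality temperature (MMT), and converts the fitted surface into
backward-perspective attributable fractions for cold and heat with Monte
Carlo empirical confidence intervals.

# Exposure: Steadman apparent temperature

Daily station records of dry-bulb temperature $Ta$ (°C), relative humidity
$RH$ (%) and wind speed $WS$ (m/s) are combined into apparent temperature

$$T_{app} = Ta + 0.33\,hPa - 0.7\,WS - 4, \qquad
  hPa = \frac{RH}{100}\, 6.105\, e^{17.27\,Ta/(237.7 + Ta)},$$

computed **per station first** and then averaged over the stations
reporting on each calendar day, giving one regional daily series. The
per-station-first order matters when stations drop out: averaging raw
inputs first would mix a nonlinear function with a changing station set.

Missing weather days are linearly interpolated when the gap is at most 3
consecutive days (a span over which tropical coastal weather is strongly
autocorrelated); longer gaps are left missing, and any case or referent day
whose 21-day exposure history touches a missing day is dropped from the
likelihood with a logged warning. Wind speed is consumed in m/s; a reader
flag converts km/h sources on ingestion.

# Design: time-stratified case-crossover

Each fatal admission acts as its own control. The referent set for a case
on day $t$ is every other day in the same calendar month and year that
falls on the same day of the week — a bi-directional, time-stratified
scheme under which every Gregorian month yields 3 or 4 referents
(mean ≈ 3.4 over a decade). Matching on weekday-within-month removes
time-invariant subject confounders by design and controls secular trends,
seasonality and day-of-week effects. Multiple deaths on one day form
distinct strata; this is equivalent to weighted aggregation for the point
estimates and keeps subgroup filtering trivial.

# Model: the crossbasis and conditional likelihood

The exposure–lag–response surface is parameterised by a tensor product of
two natural cubic spline bases. The exposure basis has 2 internal knots at
the 25th and 75th percentiles of the **whole** observed series, boundary
knots at the observed range, and no intercept (an exposure-constant effect
is not identifiable within strata). The lag basis covers lags 0–21 days
with 3 internal knots equally spaced on the log-lag scale, i.e. at
$21^{1/4}, 21^{1/2}, 21^{3/4} \approx 2.14, 4.58, 9.81$ days (computed from
the 1..21 range, with boundary knots at 0 and 21), and includes an
intercept so a constant-in-lag effect is representable. The crossbasis row
for day $t$ is

$$\mathbf{w}_t = \sum_{l=0}^{21} B_x(x_{t-l}) \otimes B_l(l),$$

built once from the whole series and looked up by date for case and
referent days alike.

The coefficients maximise the conditional logistic likelihood of the
matched sets,

$$\ell(\beta) = \sum_s \left[ \mathbf{w}_{case(s)}\beta -
  \log \sum_{d \in s} e^{\mathbf{w}_d \beta} \right],$$

the standard "binomial likelihood" of a 1:M matched case-crossover. The
maximiser is a damped Newton iteration (step halving, convergence on a
gradient max-norm of $10^{-8}$, at most 50 iterations) — appropriate
because the likelihood is concave and the dimension small (15 columns with
the default bases). The covariance is the inverse observed information at
the optimum. Columns without within-stratum variation are detected and
excluded as unidentifiable; diverging coefficient norms raise an explicit
separation error. The test suite checks the optimum against direct scalar
maximisation, a generic quasi-Newton optimiser, and conditional logistic
regression from the survival package.

# MMT and centred curves

The MMT is the argmin of the lag-cumulated exposure–response curve on a
0.1 °C grid, searched by default over the central 95% of the observed
exposure distribution (spline tails beyond that range are dominated by
sparse data and can produce spurious minima; a full-range search is
available by flag). Ties, and the degenerate all-flat curve, resolve toward
the grid median. No uncertainty interval is attached to the MMT itself.
Curves are re-centred at the MMT, so the cumulative relative risk is
exactly 1 there, with pointwise Wald intervals
$\exp(\log RR \pm 1.96\,SE)$.

# Attribution, backward perspective

For each day $t$ with a complete 21-day history the backward attributable
fraction is $1 - \exp(-\sum_l \eta(x_{t-l}, l))$, where $\eta$ is the
per-lag log relative risk relative to the MMT; the day's attributable
number is that fraction times the day's deaths. Cold and heat components
zero the terms whose lagged exposure falls on the other side of the MMT
(strict inequalities; a day exactly at the MMT contributes to neither).
Days lacking full history are excluded from numerator and denominator
alike, so components and total share one denominator. Cold + heat is only
first-order additive in the total — the identity
$1-e^{-(a+b)} \ne (1-e^{-a}) + (1-e^{-b})$ — and the package documents
(and tests) near-additivity only in the moderate-risk regime
$|\sum_l \eta| < 0.3$.

Empirical 95% intervals come from 1000 Monte Carlo draws of the
coefficient vector from $N(\hat\beta, \hat V)$ (symmetric matrix square
root applied to standard normals, so fixed seeds reproduce intervals bit
for bit), recomputing the AFs per draw with the MMT held fixed at its
point estimate, and taking the 2.5th/97.5th percentiles. Re-searching the
MMT per draw is available behind a flag for methods work; holding it fixed
matches the single-reference convention of the attribution framework.

# The synthetic-data generator

There is no public accession for individual in-hospital mortality records
of this kind, so the package ships a generator that emulates the study
conditions and makes every downstream stage testable by parameter
recovery.

*Weather.* Regional dry-bulb temperature follows an annual sinusoid
(amplitude 2 °C) plus a stationary AR(1) anomaly (coefficient 0.7,
marginal sd 1.5 °C); humidity (76.6 ± 3.4%) and wind (1.4 ± 0.5 m/s) are
truncated-normal draws. Two stations are emitted with small independent
perturbations (sd 0.3 °C) to exercise the averaging path. These defaults
put the derived apparent temperature at mean ≈ 33.5 °C with a realistic
tropical-coastal span, and were chosen once to match the published
climatology of the study region.

*Cases.* Daily deaths are Poisson with rate
$\lambda_t = 1.1 \cdot \exp(\sum_l f(x_{t-l}, l))$ where $f$ is a known
U-shaped surface: each arm is quadratic within 1 °C of the true MMT
(33 °C) and blends smoothly to a linear asymptote (cold 0.10, heat 0.07
log-RR per °C, cumulative over lags); the cold arm decays geometrically in
lag (ratio 0.75) while the heat arm is a delayed hump peaking at lag 4.
This shape is deliberately **outside** the natural-spline family the model
fits, so recovery is a fair test of the whole chain. The 1 °C blend width
gives the cumulative curve a distinct minimum; with a much wider blend the
curve is so flat near its optimum that no method could locate the MMT to
within a degree at realistic case counts. With these defaults the
generating truth implies attributable fractions of about 8–9% cold and
9–10% heat (≈ 17–18% total) on the default decade, matching the burden
scale reported for tropical in-hospital cardiovascular mortality.
Demographic attributes (59.7% male, ≈ 59% over 60, 54.9% comorbidity,
geometric lengths of stay with mean 4 days) are drawn independently of
temperature by default, so subgroup runs are null by construction unless
an interaction is configured.

*What the generator does not emulate:* reporting artefacts, multi-hospital
catchment drift, temperature-dependent admission behaviour, and
within-season humidity–temperature dependence. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
assumed data-generating law, not robustness to every real-data pathology.

# Problem sizes and numerical choices

The validation suite uses a fixed-seed synthetic decade (≈ 3,650 days,
≈ 4,900 cases) for parameter recovery; interval calibration uses 100
five-year replicate datasets with 200 Monte Carlo draws each, sizes chosen
so the whole suite completes in a few minutes while leaving the Monte
Carlo error of the coverage estimate near 2 percentage points. Other
numerical conventions: crossbasis rows are NA (and strata dropped) when
any lagged exposure is missing; the MMT grid step is 0.1 °C, one order
finer than the reporting precision of such studies; covariance matrices
are symmetrised before use and eigenvalues below $-10^{-8}$ (relative)
raise an error; the Pearson statistic scales the quasi-Poisson covariance.

# Sensitivity battery

`sensitivity_suite()` re-runs the overall analysis with four alternative
exposure-knot placements (2 equally spaced; 5/50/95; 25/50/75; 5/95
percentiles), the quasi-Poisson time-series path (log-linear in daily
counts with a 7 df/year calendar spline and day-of-week indicators — the
confounder set is a package default, configurable, since time-series
confounding is not dictated by the case-crossover design), a
length-of-stay filter (≤ 10 days), and a restricted date range, reporting
each variant's curve on the base grid and its maximum pointwise RR
divergence.

# Known limitations

- The MMT of a flat-bottomed U is weakly identified; at a few thousand
  cases its sampling scatter is of the order of ±1.5–2 °C. The AF is much
  more stable because it integrates the curve.
- AFs computed relative to an *estimated* MMT are slightly inflated
  relative to the truth at the true MMT (the argmin is chosen to minimise
  risk), an effect that shrinks with sample size and is covered by the
  Monte Carlo intervals in calibration tests.
- Wald curve intervals are pointwise, not simultaneous.
- The quasi-Poisson path shares the crossbasis with the case-crossover fit
  but is a different estimand under strong secular trends; it is provided
  for sensitivity, not as a co-primary analysis.
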