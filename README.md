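# dlnmcc

Distributed lag non-linear case-crossover models for
temperature-attributable cardiovascular mortality.

## What this package is for

Epidemiologists studying weather and health need to answer three linked
questions from daily data: *how* does the risk of death depend jointly on
temperature and on the delay since exposure; *which* temperature is
optimal for the population; and *what share* of deaths is attributable to
temperatures away from that optimum, split into cold and heat. `dlnmcc`
implements that full chain for individual-level mortality records in a
self-matched design:

- **Exposure construction.** Steadman apparent temperature
  `Tapp = Ta + 0.33·hPa − 0.7·WS − 4` with
  `hPa = (RH/100)·6.105·exp(17.27·Ta/(237.7+Ta))`, computed per weather
  station and averaged by day into one regional series.
- **DLNM crossbasis.** A tensor product of natural cubic splines over
  exposure (knots at the 25th/75th percentiles of the series) and lag
  (0–21 days, knots log-spaced), summed over the lag window:
  `w_t = Σ_l Bx(x_{t−l}) ⊗ Bl(l)`.
- **Time-stratified case-crossover fit.** Each death is matched to every
  other same-weekday day in its calendar month (3–4 referents); the
  conditional logistic likelihood
  `ℓ(β) = Σ_s [w_case β − log Σ_d exp(w_d β)]` is maximised by damped
  Newton iterations with the inverse observed information as covariance.
- **Minimum mortality temperature (MMT).** Argmin of the lag-cumulated
  curve on a 0.1 °C grid over the central 95% of the exposure
  distribution.
- **Backward attributable fractions.** Per death day,
  `1 − exp(−Σ_l η(x_{t−l}, l))` relative to the MMT, decomposed into cold
  (`x < MMT`) and heat (`x > MMT`), with empirical 95% CIs from 1000
  Monte Carlo draws of the coefficients.

Because individual hospital mortality data of this kind are not publicly
accessible, the package includes a first-class synthetic generator
(`simulate_weather()`, `simulate_cases()`) with a known U-shaped
exposure–lag–response surface, so every stage is validated by parameter
recovery, interval calibration and null-safety tests.

## Worked example

A full synthetic decade, generated and analysed end to end:

```r
library(dlnmcc)

dir <- tempfile()
bundle <- write_fixture_bundle(dir, climate = climate_spec(seed = 1),
                               surface = surface_spec(), case_seed = 2)
tapp  <- bundle$tapp                       # regional daily Tapp series
cases <- bundle$cases                      # ~4,900 individual case records

cb  <- build_crossbasis(tapp)              # 21-day lag, spline tensor basis
fit <- fit_conditional(make_strata(cases), cb)
fit
#> Conditional case-crossover fit: 15 parameter(s), 4868 strata
#> log-likelihood: -7156.098  converged: TRUE ( 3 iterations )

mmt <- find_mmt(fit, cb)
mmt
#> MMT 32.9 C (43th percentile; searched [27.4, 40.4])

deaths <- daily_death_counts(cases, dates = tapp$date)
attribution(fit, cb, deaths, mmt$mmt, n_replicates = 1000, seed = 3)
#> Attributable fraction relative to MMT 32.9 C
#>   total:  19.9% (95% CI 9.7, 28.5)
#>   cold :   9.8% (95% CI 4.8, 14.4)
#>   heat :  10.4% (95% CI 1.2, 18.4)

bundle$truth$af_total                      # the generating truth
#> [1] 0.1754426
```

The fitted MMT (32.9 °C) recovers the planted optimum (33 °C) to within a
tenth of a degree here, and the attributable-fraction interval covers the
generating truth (17.5%). `cumulative_curve()` and `lag_curve()` return
the centred exposure–response and lag–response curves with 95% CIs;
`run_pipeline(run_config(...))` drives the same analysis plus
age-and-sex and CVD-class subgroup runs from two CSV files, and
`sensitivity_suite()` re-runs it under alternative knot placements, a
quasi-Poisson time-series model, a length-of-stay filter and a restricted
study period. A thin command-line wrapper with `simulate`, `tapp`, `run`
and `sensitivity` verbs is installed under `inst/scripts/dlnmcc`.

## Package layout

| Area | Files |
|---|---|
| Exposure construction | `R/weather.R` |
| Synthetic data + truth | `R/synthetic.R` |
| Crossbasis and prediction | `R/crossbasis.R` |
| Strata and likelihoods | `R/ccfit.R` |
| MMT and curves | `R/effects.R` |
| Attributable fractions | `R/attribution.R` |
| Orchestration, subgroups, sensitivity | `R/pipeline.R` |

The methods vignette
(`vignettes/temperature-mortality-methods.Rmd`) documents the model,
the generator design, numerical conventions and known limitations.
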