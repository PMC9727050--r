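# tvdlnm

Time-varying distributed lag non-linear models (tv-DLNM) for
temperature–mortality time series, with annual adaptation indicators.

## The problem

The mortality risk associated with ambient temperature is non-linear (a U- or
V-shaped curve with a minimum at a city-specific comfort temperature) and
delayed (cold effects and short-term harvesting spread over up to three
weeks). Whether and how this exposure–lag–response surface *changes over the
years* — a rising minimum-mortality temperature, a flattening heat slope —
is how epidemiologists measure a population's adaptation to its climate.
This package fits that question end to end for daily death counts and
weather series, and is aimed at environmental-epidemiology analysts who
would otherwise assemble the pieces by hand.

## The model

For daily counts `Y_t` the package fits, by quasi-Poisson IRLS,

```
log E(Y_t) = α + cb(temp_t) + Σ_k β_k 1(dow_t = k) + γ holiday_t
           + δ PM10_(lag0–2),t + ns(RH_(lag0–2),t; 3 df)
           + ns(t; 10 df per year) + cb(temp_t) × s_t
```

where `cb` is a bi-dimensional crossbasis: a natural cubic spline in
temperature (one interior knot at the 75th percentile, boundary knots at the
observed range) tensor-combined with a natural cubic spline in lag
(intercept plus three knots equally spaced on the log-lag scale) over lags
0–21 days. The linear interaction with centred calendar time `s_t` (years)
lets the whole surface drift; slicing the coefficients at 1 July of each
year gives that year's average surface from a single fit.

From each annual slice the package derives the indicators used in this
literature:

- **cRR(x)** — the lag-cumulated relative risk of a day at temperature `x`
  versus a reference, with normal-theory 95% CIs;
- **MMT** — the percentile-constricted minimum-mortality temperature
  (argmin of the cRR curve inside the 1st–99th temperature percentiles),
  with empirical 95% CIs from a parametric bootstrap of the coefficients;
- **trend and coupling regressions** — inverse-variance weighted least
  squares of each annual indicator on year (or on annual mean temperature /
  extreme percentiles), with R², Snedecor F and Pearson r;
- a **multivariate Wald test** on the interaction coefficients, the formal
  test of "no temporal change";
- **qAIC** model scoring and a sensitivity-grid harness that compares
  alternative specifications on a common likelihood sample with a common
  dispersion.

Because the mortality microdata such analyses use are access-restricted,
the package ships a synthetic-city generator (`simulate_city()`) with a
fully known, closed-form risk surface — including a linearly drifting MMT —
so every stage of the pipeline can be validated against ground truth.

## Worked example

```r
library(tvdlnm)

sim <- simulate_city(scenario_truth(), n_years = 19, seed = 42)
m   <- tvdlnm(sim$series, "all")        # ~650 deaths/day, 6940 days
summary(m)
#> Time-varying DLNM (quasi-Poisson)
#>   stratum: all; 6940 days (2000-01-01 to 2018-12-31), 6919 rows used
#>   crossbasis: 2 x 5 = 10 columns (lag 0-21); interaction: TRUE
#>   222 parameters, dispersion 1.340, qAIC 50073.3
#>   Wald test of temporal change: chi2 = 32.150, df = 10, p = 0.0003781
```

The Wald test rejects "no change": the generator drifts its true MMT by
+0.09 °C/year. The annual indicators show the drift directly:

```r
annual_indicators(m, 2000, seed = 1)   # MMT 19.2 C (eCI 18.5-19.8)
annual_indicators(m, 2018, seed = 1)   # MMT 20.5 C (eCI 19.9-21.1)
#> 2018 cRR at P1 1.30 [1.25, 1.37]; cRR at P99 1.18 [1.14, 1.22]
```

and the weighted trend over all 19 annual MMTs recovers a positive slope:

```r
ann <- do.call(rbind, lapply(2000:2018, function(y) as.data.frame(
  annual_indicators(m, y, seed = derive_seed(42, "all", y)))))
wls_trend(ann$year, ann$mmt, pmax(ann$mmt_se, 0.05))
#> WLS trend: slope 0.0742 (se 0.0014), R2 0.994, p 2.96e-20 (*)
```

(The single-fit slope estimate sits near the generating +0.09 °C/year; its
year-to-year smoothness — hence the tiny within-replicate standard error —
comes from the linearity of the interaction. Across replicates the slope
estimator's median error is within ±0.03, as the test suite verifies.)
`run_pipeline()` wraps all of the above per stratum and writes the CSV
report; `run_sensitivity()` fits a grid of alternative specifications and
selects by qAIC. `vignettes/tvdlnm-methods.Rmd` documents the model,
its assumptions and the generator's calibration.

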