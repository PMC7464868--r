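# dustlag

Transported Saharan dust episodically raises particulate air pollution over
South Florida, and short-term particulate exposure is a suspected trigger of
acute exacerbations of COPD (AECOPD). `dustlag` is an R package for the full
exposure-reconstruction and risk-estimation chain behind that question:

* **Calibration** — collocate satellite aerosol optical depth (AOD) with
  ground PM2.5 monitors (windows of 0.75 h and 0.025°) and fit
  `PM2.5 = β0 + βa·AOD + βs·1(Apr–Sep) + β1·F1 + β2·F2 + ε`
  by OLS with HC1-robust intervals, where F1/F2 are the top two principal
  components of seven hourly meteorological variables.
* **Interpolation** — local space-time ordinary kriging (exponential
  variogram, anisotropy-scaled time metric, IDW fallback) of daily PM2.5 and
  temperature to each subject's residence for lags 0–15 days.
* **Dust identification** — dust days and low/medium/high grades from the
  LIDAR volume depolarization ratio (≤ 0.10 / 0.10–0.15 / ≥ 0.15),
  corroborated by PM10 against a rolling baseline.
* **Lagged exposure** — binary, same-day-intensity and the distributive
  inverse-time-weighted cumulative exposure
  `X_L = Σ_{l=1..L} D_l/l ÷ Σ_{l=1..L} 1/l`.
* **Risk models** — case/control logistic regressions (cases = event days,
  controls = clinic-visit days) with a cluster-robust sandwich covariance
  using the `G/(G−1)·(N−1)/(N−k)` small-sample factor, a six-model adjusted
  suite, and a 0–15 day lag sweep over all three exposure kinds.
* **Synthetic cohort generator** — all five input tables plus a cohort with
  known ground-truth odds ratios, so every stage is testable by parameter
  recovery without restricted clinical data.

## Worked example

Generate a cohort at known effect sizes (dust OR 4.955 per intensity unit,
PM2.5 OR 1.122 per µg/m³, temperature OR 1.062 per °C), assemble the
analysis frame, and refit:

```r
library(dustlag)

cfg <- synth_config(seed = 11, true_or = c(pm25 = 1.122,
                                           temperature = 1.062,
                                           dust = 4.955))
env    <- generate_environment(cfg, detail = "daily")
cohort <- generate_cohort(cfg, env)
series <- truth_exposure_series(cohort)
lags   <- build_lag_table(cohort$roster, truth_dust_days(env))
frame  <- assemble_frame(cohort$roster, lags = lags, exposures = series,
                         min_events = 2)
fits <- run_model_suite(frame)
subset(model_suite_table(fits), model == "m6")
```

```
 model            term    or lower  upper     p sig n_obs
    m6       pm25_lag1 1.192 1.088  1.306 0.000 ***   159
    m6       temp_lag1 1.191 0.999  1.421 0.051   *   159
    m6 dust1_intensity 5.100 2.594 10.026 0.000 ***   159
```

(Adjustment covariates — age, asthma, smoking, FEV1/FVC — are in the full
table.) The fully adjusted fit recovers the generating odds ratios: the
dust estimate 5.10 (CI 2.59–10.03) brackets the true 4.955, PM2.5 1.19
(CI 1.09–1.31) brackets 1.122. The 302-row frame holds 194 case rows from
subjects with ≥ 2 events and 108 zero-event controls; only the 159 rows
with lag-1 PM2.5 (satellite gaps removed) enter PM2.5 models. The lag sweep
localises the effect at the generated lag:

```r
lag_sweep(frame, lags, lags = c(0, 1, 3, 8, 15), kind = "intensity")
#>  lag    or lower upper     p n_obs
#>    0 2.094 1.414 3.102 0.000   302
#>    1 6.124 4.023 9.322 0.000   302
#>    3 1.621 1.046 2.510 0.031   302
#>    8 1.636 1.084 2.470 0.019   302
#>   15 1.627 1.093 2.421 0.016   302
```

The peak sits at lag 1 (where the effect was planted); neighbouring lags
stay mildly elevated because dust days cluster within episodes. Dust
intensity in the models is measured in units of 0.1 depolarization ratio
(a typical dust day ≈ 1.45 units); see the methods vignette
(`vignettes/dust-exposure-methods.Rmd`) for this and the other modelling
conventions.

On real inputs, `detect_dust_days()` replaces the truth labels, and
`build_exposure_series()` — kriging the `predict_pm25()` field — replaces
`truth_exposure_series()`.

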