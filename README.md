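# fieldwork

Agro-climatological risk modelling for row-crop agriculture: how do climate
scenarios change spring **field workability**, summer **drought risk**, and
**growing-season length**? The package implements the full pipeline on
synthetic data — a stochastic daily weather generator with delta-change
scenario perturbation, a 10 cm bucket model of daily soil moisture, a
threshold model of field working days (FWDs) calibrated against weekly
reports, and Thornthwaite-based water-balance, growing-degree-day and
frost-date statistics.

## The model at the core

A day is workable iff

```
WorkDay = I( SM <= Ts  and  T >= Tt )
```

where `SM` is volumetric soil moisture as a fraction of the soil's plastic
limit (PL), `T` is the daily mid-range temperature `(Tmin + Tmax)/2`, and
both comparisons are inclusive. Weekly FWD counts aggregate soil → station →
crop district (unweighted means; the state is the mean of nine districts).

`fwd_fit()` estimates the thresholds by exhaustive grid search against
weekly reports, independently for two calibration periods split at
day-of-year (DOY) 105, then connects the two optima with a straight trend
line over DOY 105–150 (extrapolated beyond, temperature threshold clamped to
[0, 10] °C) — a *trending threshold* that removes day-of-year structure from
the prediction errors. Downstream, scenarios are compared to a paired-seed
baseline through April–May FWD changes, May–August water-balance deficit
odds (`risk_odds()`), GDD (base 10 °C, cap 30 °C) and frost-date season
length.

## Worked example

Calibrate thresholds in a closed loop (reports generated from a known
schedule on synthetic weather and moisture), then compare a high-intensity
warming scenario against the paired baseline:

```r
library(fieldwork)

cfg    <- run_config(districts = c("NW", "C"), n_gen = 12, n_sub = 12,
                     seed = 20260929)
truth  <- threshold_schedule(0.80, 2.0, 0.95, 5.0, mode = "step")
study  <- make_study(cfg)
reports <- generate_fwd_reports(study$data, truth, cfg$windows)

fit <- fwd_fit(reports, study$data, grid = cfg$grid)
print(fit)
#> Workability threshold calibration (grid search)
#>   period 1: Ts = 0.800 x PL, Tt = 0.00 degC  (SSE 0 over 66 reports)
#>   period 2: Ts = 0.950 x PL, Tt = 0.00 degC  (SSE 0 over 154 reports)
#>   trend window DOY 105-150; residual DOY slope +0.0043 d/d (p = 0.134)
```

Both moisture thresholds are recovered exactly (0.80 and 0.95 × PL, SSE 0).
The temperature thresholds tie at 0 °C: in this mild training climate almost
no spring day sits below the true 2–5 °C thresholds, so many grid values fit
equally well and the deterministic tie-break reports the lowest — the
recovery tests use a cooler, more variable fixture climate where both
thresholds bind.

```r
cfg$scenarios <- default_scenarios()["high"]
res <- run_scenarios(cfg, fit$schedule, baseline_study = study)
res$deltas
#>   scenario     horizon april_may_fwd_delta risk_odds gdd_delta frost_free_delta
#> 1     high mid-century            3.113636         3  653.1673         26.95833
```

Under the stylized high scenario this small two-district ensemble gains about
3 April–May working days (warmer springs dry and warm the soil earlier),
triples its May–August deficit-month odds, adds ~650 GDD and ~27 frost-free
days relative to baseline. All deltas are paired-seed: the identity scenario
returns exactly 0 and odds exactly 1.

## Package tour

| area | functions |
|---|---|
| weather generation | `weather_params()`, `il_weather_params()`, `generate_daily_weather()`, `subsample_years()` |
| scenarios | `scenario_config()`, `apply_scenario()`, `default_scenarios()` |
| soils | `soil_profile()`, `estimate_plastic_limit()`, `estimate_water_retention()`, `scale_moisture()` |
| soil moisture | `bucket_config()`, `simulate_soil_moisture()` |
| workability | `classify_workday()`, `threshold_schedule()`, `thresholds_at_doy()`, `predict_weekly_fwd()`, `fwd_fit()` + methods, `workability_curve()`, `naive_report_probability()`, `validate_against_reports()` |
| drought & season | `thornthwaite_pet()`, `cumulative_water_balance()`, `risk_odds()`, `gdd_day()`, `frost_dates()`, `scenario_deltas()` |
| orchestration | `run_config()`, `make_study()`, `run_fit()`, `run_scenarios()`, YAML / delimited-text I/O throughout |

The methods vignette (`vignettes/fieldwork-methods.Rmd`) documents the model
assumptions, parameter defaults and units, numerical choices, what the
synthetic data do and do not emulate, and known limitations.
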