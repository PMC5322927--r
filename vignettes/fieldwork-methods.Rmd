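---
title: "Modelling field workability, drought risk and season length under climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling field workability, drought risk and season length under climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldwork)
```

## The problem

Spring field operations — tillage, planting — are only possible on days when
the topsoil is dry enough to bear traffic and warm enough to work. The number
of such *field working days* (FWDs) in April and May is a first-order economic
constraint on Midwest row-crop agriculture, and it is sensitive to climate:
wetter springs remove working days, while warming lengthens the thermal
growing season and raises summer evaporative demand and hence drought risk.

`fieldwork` implements a complete simulation pipeline for studying these
effects on synthetic data:

1. a stochastic daily weather generator with delta-change scenario
   perturbation,
2. a single-layer bucket model for daily 10 cm volumetric soil moisture,
3. a threshold model of workability calibrated against weekly FWD reports by
   exhaustive grid search (`fwd_fit()`, the package's central estimator), and
4. downstream agro-climatological statistics: Thornthwaite potential
   evapotranspiration (PET), cumulative water-balance deficits and May–August
   risk odds, growing degree days (GDD), and frost-date season length.

## The workability model

A day is classified workable iff

$$\mathrm{WorkDay} = I(\,\mathrm{SM} \le T_s \;\mathrm{and}\; \bar T \ge T_t\,),$$

where $\mathrm{SM}$ is the day's volumetric soil moisture expressed as a
fraction of the soil's plastic limit (PL), $\bar T$ is the daily mid-range
temperature $(T_{min}+T_{max})/2$, and both comparisons are inclusive.
Scaling moisture by PL lets soils of different texture share one threshold:
the classic agronomic rule of thumb puts the tillage optimum near 0.9 × PL.

Predicted weekly FWD counts aggregate hierarchically: per-soil indicator sums
over a 7-day window, averaged (unweighted) over the soils at a station, over
the stations in a crop district, and — for state values — over exactly nine
districts.

### Threshold calibration

`fwd_fit()` estimates $(T_s, T_t)$ by exhaustive grid search minimizing the
summed squared error between predicted and reported weekly FWD counts at the
district level (the level at which reports are issued). Because workability
thresholds drift over the season — soils are worked wetter later in spring —
the training reports are split at day-of-year (DOY) 105: period 1 uses
reports starting before DOY 105, period 2 those starting between DOY 105 and
150; later reports are excluded. Each period gets its own optimum, and a
straight line through (105, period-1 value) and (150, period-2 value) per
threshold becomes the fitted *trending* schedule, extrapolated linearly
outside the window. The evaluated temperature threshold is clamped into
[0, 10] °C; the moisture threshold is clamped into a [0.5, 1.2] × PL safety
band, with a warning whenever that rail is touched. The point of the trend is
diagnostic: it removes day-of-year structure from the weekly residuals, which
`fwd_fit()` verifies by regressing residuals on window mid-DOY.

Numerical choices: the default grid is $T_s \in [0.6, 1.1]$ × PL in steps of
0.01 and $T_t \in [0, 10]$ °C in steps of 0.25; ties are broken toward the
lowest $T_s$, then the lowest $T_t$ (the most conservative workability), which
together with the ascending loop order makes the search fully deterministic.
The schedule object also supports a piecewise-constant `"step"` mode —
period-1 values through the split day, period-2 values after — which is the
form the calibration itself estimates and the form used when generating
closed-loop training reports. With step mode the day DOY 105 itself belongs to
period 1, so a report window ending exactly on the split day is wholly inside
one period and noise-free closed loops close exactly.

## The weather generator

Daily weather is generated from monthly parameters: precipitation occurrence
follows a first-order two-state Markov chain (wet-day probability conditional
on the previous day wet or dry), wet-day amounts are gamma distributed, and
the daily mid-range temperature is the monthly mean curve — linearly
interpolated between mid-month anchors, wrapping across the year boundary so
December–January is continuous — plus Gaussian noise. The diurnal range
follows its own interpolated curve with a floor, which guarantees
$T_{max} \ge T_{min}$ by construction. The calendar is a fixed 365-day year
(DOY 1–365, no leap days); all downstream reasoning is in DOY.

This generator is a deliberately transparent stand-in for full
semi-empirical weather generators. It reproduces the first-order structure
that matters downstream — seasonal cycles, wet/dry persistence, skewed
wet-day amounts — but not spell-length distributions beyond first order,
inter-annual variance inflation, or solar radiation. Passing tests therefore
demonstrate the correctness and internal consistency of the pipeline, not
fidelity to any particular observed station record.

The default `il_weather_params()` climatology is typical of central Illinois
(about 40° N): July mean daily maximum near 30 °C, January means below
freezing, and roughly 1000 mm annual precipitation with a modest warm-season
peak.

Climate scenarios are *delta-change* perturbations of generator parameters —
additive monthly temperature shifts, multiplicative factors on the gamma
scale and on wet-day probabilities (clipped at 1 with a warning) — never
edits of realized series. `default_scenarios()` provides three stylized
mid-century scenarios of increasing intensity (warmer everywhere; wetter
winter/spring; neutral-to-drier summer). Mirroring large-ensemble practice,
1000 years are generated per region and scenario and 100 are randomly
subsampled for the comparatively expensive soil-moisture stage; both sizes
are configurable.

## Soils and the bucket model

Each soil profile carries texture, organic matter and four derived
parameters. Field capacity (FC), wilting point (WP) and porosity come from a
Saxton–Rawls-type regression pedotransfer on sand, clay and organic matter.
The plastic limit uses a simple linear gravimetric pedotransfer,
$PL_g = 0.12 + 0.0030\,\mathrm{clay\%} + 0.010\,\mathrm{OM\%}$ (g/g),
converted to a volumetric fraction with a configurable bulk density (default
1.3 g cm⁻³, typical of Illinois silt loams). The coefficients were chosen to
produce PL values typical of temperate agricultural silt loams and to be
strictly increasing in clay and organic matter; since workability thresholds
are expressed as *fractions* of PL, downstream results depend only on this
consistency and monotonicity, not on the absolute level.

Soil moisture comes from a single-layer (10 cm) daily bucket model, a
documented stand-in for a full soil temperature and moisture model. Each day,
in order: precipitation on days with sub-zero mid-range temperature
accumulates in a snow store released linearly (5 mm/day) on thaw days;
available water infiltrates up to remaining pore space; storage above FC
drains toward FC at a configurable daily rate (default 0.5 of the excess);
evaporation removes the day's PET share scaled by relative wetness
$(\theta - WP)/(FC - WP)$ clipped to [0, 1], floored at WP. Daily PET is the
month's Thornthwaite PET divided evenly across its days — one PET definition
serves the whole package. The model records its own fluxes, so water
conservation is testable exactly; the first simulated year is discarded by
default so spring states do not depend on the initial condition (storage
starts at FC). All comparisons in the package are scenario-relative, which
controls systematic bias in this deliberately simple closure.

## Drought and season statistics

Monthly PET uses the classical Thornthwaite formulation: heat index
$I = \sum (T_i/5)^{1.514}$ over months with $T_i>0$, exponent
$a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 + 1.792\times10^{-2} I +
0.49239$, unadjusted PET $= 16\,(10\,T/I)^a$ mm for $0 < T \le 26.5$ °C, the
standard high-temperature polynomial above 26.5 °C, zero at or below 0 °C,
adjusted by $(L/12)(N/30)$ with $L$ the mid-month day length from the
standard solar-declination approximation. Temperature-and-latitude-only PET
is the right choice here because the weather generator provides nothing
else.

The monthly *water balance* is $P - PET$, accumulated from zero at the start
of each year; a month is *in deficit* when the accumulation at its end is
negative. Ensembles are summarized by the per-month mean and 5th/95th
quantiles (linear daily interpolation between month-end points is provided
for plotting). Drought risk compares scenario to baseline as an odds ratio
of May–August deficit-month counts; a zero-baseline count returns `Inf` with
a warning, never a silent division.

Season metrics: daily GDD clamps both temperatures into [10, 30] °C before
averaging and subtracting the base, so a day contributes at most 20 °C·day
and never negative. The last spring frost is the latest DOY ≤ 182 with
$T_{min} < 0$ °C, the first fall frost the earliest DOY > 182; summaries use
per-tail 90th percentiles (the spring date later than 90 % of years and the
fall date earlier than 90 % of years), with the percentile exposed as a
parameter since a two-sided convention is equally defensible.

## Design choices worth recording

- **One station per district in scenario mode.** Scenario ensembles use one
  representative station per crop district; remaining stations are assumed to
  share its weather. This understates within-district spatial variability but
  lets every soil be used.
- **Paired seeds.** Baseline and scenario runs derive identical per-district
  seeds from the master seed, so scenario deltas contain no generator
  sampling noise from differing draws: the identity scenario yields exactly
  zero deltas and odds exactly 1. An unpaired protocol (relying on large
  ensembles, as field studies must) is available simply by changing the seed
  of one run.
- **District-level loss.** The calibration's squared error is computed on
  district-aggregated weekly predictions because that is what the reports
  measure; per-station errors are not observable in the training data.
- **Two-anchor trend.** The trend line is anchored at the two period optima
  rather than fit through week-wise optima; with one optimum per period this
  is the minimal faithful construction, and the step mode preserves the
  pre-trend form for closed-loop work.
- **April–May is DOY 91–151**, fixed once in the 365-day calendar and used
  everywhere.
- **Report noise** is integer-rounded Gaussian, truncated to [0, 7], so the
  calibration can be exercised in both exact-recovery and noisy regimes.

## What the tests show — and problem sizes

The test suite closes the loop at desk scale: reports generated from a known
step-mode schedule are recovered exactly (to grid resolution) by the
calibration on a 12-year, two-district fixture, and with report noise of
s.d. 0.5 days the recovered thresholds fall within two grid steps of the
truth in at least 90 % of 50 seeded replicates. The fixture climate for
these recovery checks is cooler and more variable than the Illinois default
so that the temperature threshold binds in both calibration periods and the
moisture threshold is swept by evaporative drydowns — identifiability, not
realism, is what a recovery test needs. Directional end-to-end checks run at
200 generated years with 30-year moisture subsamples: a wet-spring scenario
cannot gain April–May FWDs under paired seeds, a hot-dry summer raises the
May–August risk odds above 1, and uniform warming cannot shorten the
frost-free season or reduce GDD. The acceptance script
(`scripts/acceptance.R`) runs the full protocol — 30-year training
calibration, then nine districts × three scenarios at 1000 generated years
with 100-year subsamples.

Because every input is synthetic, none of this validates the model against
real crop-progress reports or real soil moisture; it validates that the
estimator recovers what generated its data, that the physics respects its
invariants (mass balance to 1e-9, bounds, monotonicities), and that the
pipeline's comparative statics have the right signs.

## Known limitations

- The bucket model has no soil-temperature state, layering, runoff routing
  or irrigation; frozen-soil handling is a simple snow-store heuristic.
- The generator's monthly parametrization cannot represent sub-monthly
  regime changes (e.g. a wetter early April but drier late April within one
  month).
- Thornthwaite PET responds only to temperature and day length; humidity- or
  wind-driven drought signals are invisible to it.
- With a mild training climate the temperature threshold can be only weakly
  identified (few spring days near it); the grid search then reports the
  lowest tied value by its deterministic tie-break rule.
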