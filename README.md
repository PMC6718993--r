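# heatwarn

Occupational heat-stress forecasting and warning toolkit for R.

Outdoor workers are affected by environmental heat well below the levels
that drive excess mortality in the general population: performance drops,
dehydration and cardiovascular strain build up over consecutive hot days,
and the safe workload depends on the individual — body size, physical
effort, clothing, sun or shade exposure, and whether the worker is
acclimatized to heat. `heatwarn` implements the computational chain of a
station-based occupational heat–health warning system for users of
extended-range ensemble weather forecasts: forecasters and occupational-
health researchers who want to turn multi-member meteorological forecasts
into personalized, probabilistic heat-risk guidance, and to verify how much
skill that guidance actually has.

## What it computes

**Heat stress index.** The Wet-Bulb Globe Temperature,

- in the sun: `WBGT_sun = 0.7 T_nwb + 0.2 T_g + 0.1 T_a`
- in the shade: `WBGT_shade = 0.7 T_nwb + 0.3 T_g`

where the natural wet-bulb temperature `T_nwb` (evaporative cooling) and
the black-globe temperature `T_g` (radiant load) are solved from their
energy balances: a Liljegren-type globe/wick formulation for sun exposure
and a wind-dependent natural-to-psychrometric wet-bulb relation
(Bernard-type) for shade. Inputs are the standard daily variables —
maximum air temperature, mean dew point, mean wind speed, maximum solar
irradiance — yielding the day's maximum heat stress.

**Bias correction.** Empirical quantile mapping (EQM) calibrated per
station, variable and lead-week bin between a multi-year ensemble hindcast
and the station observation archive, including the mapping of forecast
daily-mean irradiance onto the observed daily-maximum scale. Stations with
more than 20% missing observations are dropped by the QC filter.

**Personal risk.** Du Bois body surface area
`BSA = 0.20247 w^0.425 h^0.725`, metabolic rate `MR = BSA × level × 50` W,
NIOSH limits `RAL = 59.9 − 14.1 log10 MR` (unacclimatized) and
`REL = 56.7 − 11.5 log10 MR` (acclimatized), clothing adjustment (CAV),
risk level `100 × WBGT_eff / limit` %, and the four bands
(≤80 not significant, 80–100 low, 100–120 moderate, ≥120 high) with break
and hydration recommendations. A worker becomes acclimatized after five
days of at least moderate forecast risk.

**Products and verification.** Weekly maximum probability of exceeding a
WBGT threshold (operational default: 27 °C in the sun) for the four
upcoming Monday–Sunday weeks; 5-day personal risk with e-mail-style alert
records; a 41-day planning calendar (days 6–46); and ensemble CRPS / CRPSS
verification against raw forecasts or a 20-member climatological
pseudo-ensemble, aggregated into lead weeks (days 5–11, 12–18, 19–25,
26–32).

A synthetic-data module generates station networks, 20-year observation
archives and biased 51-member hindcasts with known structure, so the whole
pipeline runs and is testable without any external data.

## Worked example

```r
library(heatwarn)

cfg <- synth_config(seed = 2, n_stations = 3, n_years = 20, n_members = 51)
sys <- simulate_system(cfg, inits_per_year = 2)

store <- fit_eqm_store(sys$observations, sys$hindcast)
init  <- max(sys$hindcast$init_date)                     # 2017-09-28
fc    <- correct_ensemble(sys$hindcast[sys$hindcast$init_date == init, ], store)
wfc   <- ensemble_wbgt(fc, sys$stations)

weekly_exceedance(wfc[wfc$station_id == "ST0001", ], init)
#>   station_id week week_start   week_end probability threshold exposure
#> 1     ST0001    1 2017-10-02 2017-10-08   0.1764706        27      sun
#> 2     ST0001    2 2017-10-09 2017-10-15   0.0000000        27      sun
#> 3     ST0001    3 2017-10-16 2017-10-22   0.0000000        27      sun
#> 4     ST0001    4 2017-10-23 2017-10-29   0.0000000        27      sun
```

In the first upcoming week, 17.6% of the 51 corrected members push the
daily maximum sun WBGT above 27 °C on at least one day; later weeks stay
cool. The personalized short-term forecast for a 1.75 m / 70 kg worker
doing high physical work in the sun:

```r
profile <- worker_profile(height = 1.75, weight = 70, activity = "high",
                          environment = "sun", station_id = "ST0001")
profile
#> Worker profile
#>   1.75 m, 70 kg (BSA 1.85 m2), activity class 4 -> MR 370 W
#>   environment: sun, clothing: conventional (CAV +0.0 degC)
#>   unacclimatized (limit RAL = 23.69 degC-WBGT), qualifying days: 0

st <- short_term_risk(profile, wfc, init)
st$assessments[, c("date", "wbgt_raw", "risk_pct", "band")]
#>         date wbgt_raw risk_pct            band
#> 1 2017-09-29 17.29432 72.98848 not_significant
#> 2 2017-09-30 18.01518 76.03078 not_significant
#> 3 2017-10-01 20.98572 88.56760             low
#> 4 2017-10-02 18.13711 76.54538 not_significant
#> 5 2017-10-03 21.11252 89.10271             low
st$alert
#> NULL
```

The median member's WBGT stays below this worker's alert limit
(RAL = 23.69 °C for MR = 370 W), so the five days classify as
not-significant to low risk and no alert record is produced; days at
100% of the limit or above would be banded moderate/high, trigger the
alert, and — after five such days — switch the worker to the higher
acclimatized limit (REL = 27.2 °C).

The same chain is available from a shell via the installed CLI
(`inst/cli/heatwarn`): `simulate`, `calibrate`, `forecast`, `wbgt`,
`risk`, `products`, `verify`.

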