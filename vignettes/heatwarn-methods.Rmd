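---
title: "Methods behind heatwarn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind heatwarn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`heatwarn` chains five stages: synthetic (or user-supplied) station data,
WBGT computation, empirical quantile-mapping bias correction, a
personalized risk engine, and probabilistic verification. This vignette is
the package's own account of the science in each stage: the models and
their assumptions, the parameters that matter, the numerical choices, and
what the synthetic study conditions do and do not establish.

## 1. The heat stress index

The Wet-Bulb Globe Temperature combines three component temperatures:

* `WBGT_sun  = 0.7·T_nwb + 0.2·T_g + 0.1·T_a` (direct short-wave load),
* `WBGT_shade = 0.7·T_nwb + 0.3·T_g` (no direct short-wave load),

so the natural wet bulb — the evaporative-cooling proxy — always carries
70% of the index, and the globe term carries 20% (sun, alongside a 10% air
term) or 30% (shade). The two weightings are the standard sun/shade
conventions of the occupational WBGT literature; the package freezes them
in `wbgt_combine()` and audits them in the test suite (unit sum,
component coefficients, translation equivariance).

**Globe temperature** (`globe_temperature()`) balances absorbed direct and
diffuse short-wave radiation and long-wave exchange against convective
loss and re-emission for a standard 5.08 cm black globe (emissivity 0.95,
albedo 0.05), with a sphere Nusselt-number correlation
`Nu = 2 + 0.6·Re^0.5·Pr^(1/3)` for the transfer coefficient. Sky
emissivity defaults to `min(1, 0.575·e^0.143)` with `e` the ambient vapor
pressure in hPa; `emis_sky = 1` gives an isothermal radiative environment
(useful for the degenerate check `S = 0 ⇒ T_g ≈ T_a`).

**Natural wet bulb in the sun** (`natural_wet_bulb_sun()`) solves the
energy and mass balance of a ventilated wetted wick (0.7 cm × 2.54 cm
cylinder, emissivity 0.95, albedo 0.4) including its solar load, with a
cylinder correlation `Nu = 0.281·Re^0.6·Pr^0.44`, the latent-heat and
vapor-diffusivity temperature dependences, and the `(Pr/Sc)^0.56`
heat–mass-transfer analogy.

**Natural wet bulb in the shade** (`natural_wet_bulb_shade()`) uses the
wind-dependent relation `T_nwb = T_a − C(v)(T_a − T_pwb)` with
`C(v) = min(1, 0.96 + 0.069·log10 v)`: in calm air the natural wet bulb
sits closer to the dry bulb; above about 3 m/s it coincides with the
psychrometric wet bulb `T_pwb`, itself solved from the psychrometer
balance `e_sat(T_w) − e = 6.67·10⁻⁴·p·(T_a − T_w)`. This captures the
characteristic behavior that WBGT is very wind-sensitive below ~1 m/s and
nearly wind-insensitive above.

Saturation vapor pressure uses the Buck-type form
`6.1121·exp(17.502 t/(240.97+t))` hPa, valid for −60…60 °C.

### Numerical choices

* **Solvers.** Both balances are solved by a vectorized damped fixed point
  (damping 0.9·old + 0.1·new, tolerance 10⁻⁴ °C on the fixed-point
  residual, cap 200 iterations). Any element that has not converged — or
  leaves the finite range — falls back to bracketed root finding
  (`uniroot`) on the explicit balance residual. The tight tolerance keeps
  the energy-balance residual at the returned solution below 10⁻³ in
  temperature units, which the test suite asserts.
* **Wind floor.** 0.13 m/s before any transfer or logarithmic term: calm
  air would otherwise make the correlations singular, and measured winds
  below the floor are within anemometer noise anyway.
* **Solar geometry.** The platform works from daily aggregates, not
  instantaneous geometry, so when no zenith angle is supplied the solvers
  assume the high sun implied by a daily-maximum irradiance (zenith 30°)
  and a fixed direct fraction `fdir = 0.75`; surface albedo 0.45.
* **Pressure.** Stations carry altitude but no pressure record; the
  standard-atmosphere barometric formula (`station_pressure()`) supplies
  it.
* **Degenerate inputs.** `daily_max_wbgt()` clamps the daily-mean dew
  point at the daily-maximum temperature (daily aggregates of different
  statistics can cross), returns a shade value with a missing sun value
  when irradiance is missing, and propagates missingness when any of
  temperature, dew point or wind is absent.
* **Shade globe.** Whether the shade globe should be solved radiatively
  at `S = 0` or simply set to the air temperature is a genuinely open
  convention; the radiative solution is the default and
  `globe_mode = "air"` exposes the simpler choice.

## 2. Bias correction

`eqm()` fits the empirical quantile map between a forecast sample and an
observation sample: paired empirical quantiles on a probability grid, by
default the 99 percentiles 0.01…0.99 — fine enough to follow the seasonal
distributions, coarse enough that each grid point is estimated from many
values. Application (`predict.eqm()`) interpolates piecewise-linearly
between paired quantiles; beyond the outermost grid points the correction
of the nearest extreme quantile is applied as a constant offset, so
extreme forecasts are corrected but never linearly extrapolated into
implausible values. The mapping is monotone by construction.

Maps are fitted per station, variable and **lead-week bin** (days 1–7,
8–14, …, 43–46), pooling all members and init dates inside the bin: lead
dependence is retained at a resolution where each bin still holds
thousands of pairs, while per-day fitting would starve the samples. The
calibration pools the whole warm-season hindcast set rather than a moving
calendar window around each target date; at the package's problem sizes a
per-date window would multiply the number of fits for little gain, and the
round-trip and bias-recovery tests exercise exactly the pooled behavior.
Pairs with a missing observation are dropped before fitting; a fit needs
at least `min_n = 100` values on each side and rejects a constant forecast
sample.

The irradiance map is special: the forecast provides daily *mean*
irradiance while the index needs the daily *maximum*, so
`fit_radiation_max_map()` maps the forecast daily-mean distribution onto
the observed daily-max distribution (non-negative outputs enforced). Wind
corrections are likewise clamped at zero.

`correct_ensemble()` refuses to run with a missing map — a silent
fallthrough to uncorrected members would defeat the purpose — and names
the exact (station, variable, bin) gap.

Station quality control (`qc_filter_stations()`) drops stations whose
missing-cell fraction over the four variables **strictly exceeds** 0.20
over the evaluation period (a station at exactly 20% is retained), with
the period configurable and defaulting to the archive span.

## 3. The personalized risk engine

From the registration fields the engine derives, in order: Du Bois body
surface area `BSA = 0.20247·w^0.425·h^0.725` (w in kg, h in m); metabolic
rate `MR = BSA·level·50` W on the 1–5 activity scale (1 = resting); the
NIOSH limits `RAL = 59.9 − 14.1·log10 MR` and `REL = 56.7 − 11.5·log10 MR`
(REL > RAL for every MR above 17 W — the two lines cross at
`log10 MR = 3.2/2.6`); the clothing-adjusted effective WBGT
`WBGT_eff = WBGT + CAV`; the risk level `100·WBGT_eff/limit` %; and the
band (≤80 not significant, 80–100 low, 100–120 moderate — inclusive at
100 —, ≥120 high).

Design choices the published material leaves open:

* **Registration labels.** The platform-style registration offers four
  activity labels while the metabolic-rate formula uses the five-class
  scale with class 1 = resting; `worker_profile()` maps
  low/moderate/high/very_high to classes 2–5 (a worker is not resting).
* **Ensemble collapse.** How 51 members become one displayed personal
  value is not prescribed; the engine uses a configurable quantile,
  default the median member, with e.g. 0.75 available for risk-averse
  users.
* **CAV table.** Clothing adjustment values are cited to the occupational
  standards but not printed; the package ships an editable default
  (conventional one-layer = 0, cloth coveralls 0, SMS coveralls +0.5,
  polyolefin coveralls +1, double layer +3, vapor barrier +11 °C) both in
  code (`default_cav_table()`) and as JSON under `extdata`.
* **Acclimatization.** A new profile is unacclimatized (RAL). Each
  forecast day with at least moderate band increments a counter; at five
  qualifying days the profile flips to acclimatized and subsequent
  assessments use REL. Qualifying days need not be consecutive — the
  published rule says only "5 days with at least moderate risk during the
  warm season" — but 30 days without a qualifying day reset the counter
  and the state, which operationalizes "within a season" without a
  de-acclimatization model. Assessments must be processed in date order.
* **Banding edge.** A sub-zero effective WBGT would give a negative
  percentage; the engine clamps the risk level at 0 (no heat risk), so the
  band partition stays exhaustive.
* **Band-table reconstruction.** `table1_boundary()` reconstructs the
  published band boundaries as 80/100/120% of RAL/REL at the reference
  metabolic rates (180/300/415/520 W — the published reference rates,
  which are the standard activity-class rates rather than
  `MR = BSA·level·50` at a typical BSA), rounded to the nearest 0.5 °C.
  The printed table's own rounding is not uniform: 13 of the 32 cells
  match nearest-0.5 rounding exactly, and all 32 lie within 0.5 °C of the
  unrounded formula value; the test suite pins both facts, and the live
  engine always uses the unrounded limits.
* **Hydration codes.** The published drop icons are only partly
  recoverable from the table text; the shipped mapping (1 = ~0.5 L/h,
  2 = ~1 L/h, 3 = >1 L/h; escalating with band, higher for the
  high/very-high metabolic classes, 3 everywhere in the high band) is
  monotone in the band within every class and is documented as
  platform-configurable rather than physiological truth.

## 4. Products

* **Weekly exceedance** (`weekly_exceedance()`): per station and
  Monday–Sunday week, the maximum daily probability that the member WBGT
  exceeds the threshold (default 27 °C, sun exposure). Exceedance is the
  **strict** member fraction — for continuous member values a tie at the
  threshold has probability zero, and the convention is documented.
  Weeks anchor at the first Monday on or after the init date; partial
  leading days belong to no week and are excluded from the four-week
  product.
* **Short-term risk** (`short_term_risk()`): one assessment per day for
  days 1–5, advancing the acclimatization state in date order, plus an
  alert record (`alert_check()`) exactly when some day reaches at least
  the moderate band — the rule is verified against brute-force
  enumeration of all 4⁵ band patterns.
* **Long-term calendar** (`long_term_calendar()`): banded days 6–46 (41
  entries) with the worker's *current* state; a planning product does not
  advance the state machine.
* **Nearest station** (`nearest_station()`): great-circle distance plus an
  altitude penalty of 1 km per 100 m difference — "nearest with similar
  altitude" needs an exchange rate, and 1 km/100 m roughly matches the
  relative temperature gradients; exact ties break deterministically by
  station id.

## 5. Verification

`crps_ensemble()` implements the kernel form
`mean|xᵢ − y| − ½·mean|xᵢ − xⱼ|`, which equals the integral of the squared
difference between the ensemble CDF and the observation step function; the
test suite checks that equivalence to 10⁻⁴ against exact piecewise
integration on random small ensembles. A single-member ensemble scores the
absolute error, and the score is zero exactly for a degenerate ensemble at
the observation.

The climatological reference (`climatological_reference()`) mimics an
ensemble with one member per archive year at the same calendar day; a
±7-day window, taking each year's non-missing value closest to the target
day, keeps exact-day gaps from destroying members while staying inside the
same synoptic season.

Weekly skill: daily CRPS values of forecast and reference are averaged
separately within the lead weeks (days 5–11, 12–18, 19–25, 26–32) and one
skill score `1 − CRPS_fc/CRPS_ref` is formed **from the weekly means** —
not by averaging daily skill scores, which is a different (and less
stable) statistic; a two-day counterexample in the tests separates the
two conventions.

## 6. Synthetic study conditions

The generator (`synth_config()`, defaults chosen once) emulates the
operational setting at station scale: a 20-year daily archive; a 51-member
ensemble out to 46 days initialized Mondays and Thursdays; additive
forecast biases of +2 °C (tmax), +1 °C (dew point), +0.5 m/s (wind) and
+50 W/m² (irradiance); Gaussian member noise growing with lead by a
factor 1.02 per day; and an irradiance forecast that is a daily-mean-like
product (0.45 of the truth's daily maximum) so the mean-to-max map has a
real job. The truth process per variable is a seasonal sinusoid plus AR(1)
noise (tmax: amplitude 12 °C, φ = 0.7, σ = 3 °C) — the simplest process
with realistic autocorrelation for quantile-mapping tests — with the dew
point built as temperature minus a positive depression, so physical
constraints hold by construction. Missingness is injected uniformly at
random per variable cell, which is sufficient for the 20% QC-filter
behavior. Calibration sets use 2 warm-season init dates per year
(40 inits over 20 years); the full-pipeline test runs 5 stations ×
20 years × 51 members × 46 leads, and the bias-recovery check pools
several thousand pairs per lead bin.

What passing these tests does **not** show about real data: the generator
has no spatially correlated fields, no synoptic regimes, no
non-stationary biases, no conditional (e.g. cloud-dependent) radiation
errors and no blocked missingness — so the results demonstrate that the
chain is implemented correctly and recovers known structure, not that any
particular real-world skill level will be achieved.

## 7. Known limitations

* Daily resolution only; no intra-day (hourly) heat-stress cycle.
* No indoor/artificial radiant-source environments, and no alternative
  thermal indices.
* Health conditions and medication are out of scope — assessments assume
  a healthy worker.
* The EQM is univariate per variable; cross-variable dependence of
  forecast errors is not corrected.
* The acclimatization model is the operational 5-day counting rule, not a
  physiological model.
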