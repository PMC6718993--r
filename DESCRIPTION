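Package: heatwarn
Title: Occupational Heat-Stress Forecasting and Warning Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds station-level occupational heat-health warnings from
    ensemble weather forecasts. Computes Wet-Bulb Globe Temperature (WBGT)
    for sun and shade exposure from standard meteorological variables,
    bias-corrects multi-member extended-range forecasts against a station
    observation archive by empirical quantile mapping, derives personalized
    heat-risk levels from NIOSH recommended alert and exposure limits with
    clothing adjustment and an acclimatization state machine, produces
    weekly exceedance-probability, short-term risk and long-term calendar
    products, and verifies the probabilistic forecasts with the continuous
    ranked probability (skill) score. A synthetic-data module generates
    station networks, observation archives and biased ensemble hindcasts so
    the whole pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
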