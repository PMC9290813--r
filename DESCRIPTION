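Package: aeroalert
Title: Forecast-Triggered Selection of Bird Migration Action Nights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates radar-like nocturnal bird migration profiles with
    weather-driven pulsed passage, integrates 30-minute altitude-binned
    reflectivity profiles into nightly migration traffic rates (birds per
    kilometer per night), trains seasonal gradient-boosted tree forecasts of
    migration intensity from weather covariates under a leave-one-year-out
    protocol, and compares dynamic (forecast-triggered) against fixed-window
    strategies for choosing conservation action nights that capture a target
    fraction of seasonal migratory passage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
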