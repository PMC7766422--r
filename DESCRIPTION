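Package: metpowr
Title: Metabolic Power from GPS Tracking in Soccer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates instantaneous and average metabolic power of soccer
    players from 10 Hz GPS speed traces using the equivalent-slope energy-cost
    framework of di Prampero, re-parameterised for elite players running on
    grass (flat-running cost 4.66 J/kg/m). Implements the direct-calorimetry
    reference: breath-by-breath oxygen-uptake processing and the
    aerobic/alactic/lactic energy partition; calibrates the indirect GPS
    estimate against the direct one with ordinary least products regression,
    bootstrap confidence intervals and prediction intervals; computes
    external-load summaries (speed and power band occupancy, high-intensity
    time fractions, power bouts, changes of direction); and ships a simulator
    of a soccer-specific intermittent exercise circuit with coupled
    first-order oxygen-uptake kinetics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
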