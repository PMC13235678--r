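Package: ccoheat
Title: Time-Stratified Case-Crossover Analysis of Daily Temperature and
    Acute Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover studies of daily
    ambient temperature and acute adverse events.  Builds matched strata
    (same location, weekday, calendar month and year), links each stratum
    day to gridded daily weather by nearest grid cell, and estimates
    exposure-response via a purpose-built Newton-Raphson conditional
    logistic regression with linear or natural cubic spline exposure
    terms selected by AIC.  Includes odds-ratio extraction at named
    exposure percentiles with delta-method intervals, neighborhood
    deprivation stratification via the Index of Concentration at the
    Extremes (ICE) with national terciles and incidence rates, Cochran's
    Q heterogeneity tests across strata, and a seeded synthetic-data
    generator (events, weather grid, tract tables) with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
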