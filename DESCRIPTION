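Package: pondlogger
Title: Behaviour and Time-Budget Analysis for Multi-Sensor Biologging of
    Freshwater Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for archival tags deployed on freshwater
    turtles that record tri-axial acceleration at 10 Hz together with
    temperature, pressure and light at 1 Hz.  Decomposes acceleration into
    static and dynamic components, computes VeDBA and body angles, segments
    each 24-h cycle into Night, Morning, Midday and Evening phases from
    light, temperature and pressure thresholds, detects breathing bouts,
    basking, diving and nest-digging events, infers the occupied water
    stratum by regressing tag temperature on reference series, and builds
    daily time and activity budgets.  Includes a seeded multi-sensor
    deployment simulator with ground-truth behaviour labels for validating
    every stage, and a logistic model of daily basking occurrence driven by
    weather covariates with backward AIC selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
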