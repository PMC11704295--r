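Package: heatmort
Title: Two-Stage Heat-Mortality Projections at Global Warming Levels with
    a COVID-19 Mortality Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-stage time-series analysis of temperature and
    mortality and its projection to global warming levels (GWLs). Stage one
    fits location-specific quasi-Poisson distributed lag non-linear models
    (DLNM) and reduces them to cumulative temperature-mortality curves with a
    minimum mortality temperature (MMT) reference; stage two pools reduced
    coefficients across locations by multivariate REML meta-regression and
    derives best linear unbiased predictions (BLUPs). Climate-model daily
    temperatures are bias-corrected by empirical quantile mapping and sliced
    into 20-year GWL windows; heat-attributable deaths and annual
    heat-mortality fractions are projected with Monte-Carlo empirical
    confidence intervals. A comparison module expresses projected heat
    mortality in years needed to equal one year of COVID-19 deaths. A
    synthetic-data generator with analytically known ground truth makes every
    stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml,
    tools,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
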