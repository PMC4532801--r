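Package: vernaltherm
Title: Vernalization Thermal-Response Surfaces and Effective-Time Accumulation
Version: 0.1.0
Authors@R:
    person("Vernaltherm", "Maintainers", email = "maintainers@vernaltherm.org",
           role = c("aut", "cre"))
Description: Tools for analysing the temperature dependence of vernalization,
    the acceleration of flowering by prolonged cold. Builds genotype-specific
    flowering-time response surfaces over (temperature, duration) from
    constant-temperature cabinet experiments, accumulates vernalization-
    effective time from hourly or thrice-daily climate records under
    configurable temperature windows (e.g. the legacy 0-6 degree hourly window
    or a 0-15 degree daily-mean window), and predicts flowering of field
    transplant cohorts by matching field interval mean temperatures to
    constant-temperature conditions. Includes a synthetic autumn-weather and
    flowering-time generator so every stage of the pipeline can be exercised
    without external data, plus qPCR expression and ChIP double-ratio
    normalization helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
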