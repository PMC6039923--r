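Package: lifelimits
Title: Flexible Upper Limits of Human Lifespan from Life-Table Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the maximum survivable age (MSA) by fitting log-linear
    models to the age-specific probability of death in life tables and
    projecting the fit to q = 1, with delta-method confidence intervals and
    population-year time series. Provides diagnostics for the data artifacts
    that can manufacture spurious lifespan limits: integer rounding of l(x)
    survivorship on a 100,000 radix, log(0)-as-log(1) substitution in
    log-linear regressions, terminal age caps, and the pooling of record
    databases with shifting country coverage. Includes readers and writers for
    HMD-style 1x1 life tables and supercentenarian death-record panels, a
    Gompertz(-Makeham) synthetic-data generator, maximum-reported-age-at-death
    trend analyses (segmented linear trends and robust LOWESS smoothing), and
    a seeded experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
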