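Package: equicov
Title: Health-Inequality Measurement for Binary Coverage Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survey-weighted disaggregation of a binary health-coverage
    indicator (such as DPT3 immunization among children aged 12-23 months)
    across equity stratifiers, with the six standard summary measures of
    health inequality (difference, ratio, slope and relative indices of
    inequality, population attributable risk and fraction), concentration
    and Lorenz curves with concentration and Gini indices, a confidence
    interval overlap rule for cross-year trend assessment, and a two-level
    random-intercept logistic model of individual and community
    determinants.  Includes a synthetic generator for two-stage cluster
    survey microdata so every stage of the pipeline can be exercised and
    validated without restricted survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    purrr,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
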