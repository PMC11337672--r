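Package: dupreg
Title: Drug Utilisation in Pregnancy from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacoepidemiological drug-utilisation studies of
    pregnancy cohorts built from electronic-health-record style tables.
    Carves pregnancy episodes into labelled exposure windows (pre-conception,
    trimesters, post-partum), classifies prevalent and incident (new-user,
    washout-based) exposure from prescription date ranges, estimates per-1000
    prevalence and cumulative incidence with exact binomial or Wald confidence
    intervals, builds monthly prescription-prevalence series, and evaluates
    regulatory interventions by segmented Poisson interrupted-time-series
    regression with lag-based autocorrelation handling and counterfactual
    contrasts. Ships a synthetic-EHR generator with recorded ground truth so
    the whole pipeline is testable without access to confidential data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
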