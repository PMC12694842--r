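Package: rrda
Title: Curation and Trend Analysis of Longitudinal Primary Care Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds a research-ready data asset (RRDA) from raw general
    practice event data: six-step curation against GP registration history
    (cleaning, registration-based validation with practice-identifier
    correction, exact and GP-to-GP de-duplication, clinical-code resolution,
    three-table normalisation), a prioritised clinical-code look-up spanning
    Read V2, SNOMED-CT and supplier-local code systems, a four-layer
    patient-practice interaction classifier with person-day activity
    categorisation, and the downstream analyses: binomial generalised
    additive mixed models of population coverage and negative-binomial
    GAMMs of monthly activity rates with cyclic seasonal splines and AR(1)
    errors. Includes a synthetic GP-data generator with controlled
    corruption injection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    lubridate,
    mgcv,
    nlme,
    glmmTMB,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
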