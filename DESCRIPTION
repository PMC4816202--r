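Package: scadcost
Title: Healthcare Utilization and Cost Modelling for Stable Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model long-term healthcare utilization and costs in
    stable coronary artery disease (SCAD) cohorts built from linked
    electronic health records. Provides a synthetic cohort generator
    (baseline covariates, competing-risk events on a 90-day cycle grid,
    gamma-distributed period costs with event increments), cohort entry and
    censoring-exclusion rules, first-year and post-event cost and
    utilization summaries, gamma generalized linear cost regression with
    multiple imputation pooled by Rubin's rules, a 90-day panel cost model
    with time-since-event cost bands, a six-state Markov transition model,
    and a lifetime cost projection engine with discounting, risk-decile
    stratification and a microsimulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    sandwich,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
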