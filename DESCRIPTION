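Package: prolight
Title: Traffic-Light Feedback on Patient-Reported Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores EORTC QLQ-C30 and HADS questionnaires from item-level
    responses, compares scale scores against age- and sex-matched reference
    statistics from a lymphoma cohort and a general-population cohort,
    classifies each score into traffic-light categories using clinically
    relevant difference thresholds, and renders per-patient bar-chart
    feedback reports with narrative text. Also provides the accompanying
    study statistics (exact contingency-table tests, two-sample t tests,
    ANCOVA with age and sex covariates, clinical-relevance labelling) and a
    synthetic cohort generator so the whole pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
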