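Package: dietsense
Title: Validation of Mobile Food-Record Energy Intake Against Armband Energy
    Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing dietary records collected with a mobile food
    record in adolescents and validating reported energy intake against a
    wearable reference. Computes energy and nutrient intake from per-meal food
    records using a portion-aware food-composition database; estimates basal
    metabolic rate with Schofield's weight-based equations and total energy
    expenditure from a five-level physical-activity question; derives reference
    total energy expenditure from minute-level armband traces with basal-rate
    imputation of off-body time; scores lifestyle and eating-behaviour
    questionnaires with declared imputation rules; and runs the full evaluation
    pipeline (day-level inclusion filters, misreporting classification against
    a plausibility band, Bland-Altman agreement, rank correlations, and
    stepwise regression of reporting accuracy on participant factors). A
    seeded synthetic-study generator produces complete cohorts (food database,
    anthropometrics, diet records, armband traces, questionnaires) with
    configurable reporting bias so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    ggplot2,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
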