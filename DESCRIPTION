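Package: teecea
Title: Cost-Effectiveness Modelling of Modified Transesophageal
    Echocardiography Screening Before Cardiac Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-part decision-analytic model for evaluating diagnostic
    strategies that detect ascending-aorta atherosclerosis before cardiac
    surgery: a diagnostic decision tree translating test sensitivity and
    specificity into per-strategy probabilities of surgical adaptation,
    stroke and early death, feeding a three-state Markov cohort model
    ('no complications', 'post stroke', 'dead') that accumulates
    discounted costs, life-years and QALYs over a lifetime horizon.
    Includes parameter distributions for probabilistic sensitivity
    analysis, EuroSCORE-based early-mortality stratification by
    atherosclerosis status, incremental cost-effectiveness ratios with
    dominance quadrants, cost-effectiveness planes with bivariate
    confidence ellipses, acceptability curves, and a Gompertz-Makeham
    synthetic life-table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
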