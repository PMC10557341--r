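Package: sleepmr
Title: One-Sample and Factorial Mendelian Randomization for Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomization with a Cox
    proportional-hazards second stage (two-stage predictor substitution with
    bootstrap standard errors), 2x2 and continuous factorial Mendelian
    randomization with relative excess risk due to interaction (RERI), genetic
    risk score construction and harmonization, summary-statistic sensitivity
    estimators (IVW, MR-Egger, weighted median, weighted mode), proportional
    hazards diagnostics, and confounder association scans. Includes a synthetic
    cohort generator that emulates the instrumental-variable structure of
    biobank sleep-trait studies (genotypes in Hardy-Weinberg proportions,
    liability-model binary exposures, censored proportional-hazards outcomes
    with confounding and pleiotropy) so every analysis stage can be validated
    without access to restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
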