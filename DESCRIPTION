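Package: neuroprog
Title: Prognostic Modelling of Atrophy and Hypometabolism Patterns in Memory-Clinic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic-biomarker analysis of mixed memory-clinic
    cohorts. Computes intracohort z-scores of regional MRI volumes and
    [18F]FDG-PET standardized uptake value ratios, classifies lobe-wise
    atrophy/hypometabolism patterns and anatomical congruence levels, counts
    abnormal neurodegeneration markers, and relates them to 1-year clinical
    progression through logistic regression with Woolf/Wald odds ratios and
    confidence intervals, repeated stratified k-fold cross-validation with
    balanced accuracy, and eigensystem multicollinearity diagnostics. Includes
    a synthetic-cohort generator with a latent-severity structure and
    contingency-table fixtures, plus a configurable sensitivity-analysis grid
    over dichotomization thresholds, lobe-count cut-offs, outcome definitions
    and adjustment sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
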