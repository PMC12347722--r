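Package: sepsisbn
Title: Sepsis Prediction from Postoperative Biomarkers via ROC Analysis
    and a Discrete Bayesian Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic-accuracy analysis of postoperative soluble
    triggering receptor expressed on myeloid cells-1 (sTREM-1) as a sepsis
    biomarker in a pediatric post-cardiac-surgery cohort, and its
    combination with C-reactive protein and white blood cell count in a
    discrete Bayesian network. Provides empirical ROC curve construction
    with the Youden-optimal cutoff and likelihood ratios, trapezoidal and
    concordance AUC with Hanley-McNeil confidence intervals, recovery of a
    labeled cohort from a published ROC coordinate table (including
    monotonicity repair of typographical errors), frequency-based
    conditional probability table estimation, exact posterior inference by
    enumeration, and a seeded synthetic-cohort generator for
    parameter-recovery experiments.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
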