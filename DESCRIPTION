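Package: exlr
Title: Diagnostic Gene Signatures from Plasma Extracellular Vesicle Long RNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates liquid-biopsy diagnostic gene signatures from
    extracellular-vesicle long RNA (exLR) sequencing count matrices. Covers
    length-aware TPM quantification restricted to long-RNA biotypes, sample
    quality control by median inter-sample correlation, empirical-Bayes
    moderated-t differential expression with Benjamini-Hochberg adjustment,
    candidate filtering, minimum-redundancy maximum-relevance (mRMR, MIQ
    scheme) feature ranking, incremental feature selection with support vector
    machines scored by leave-one-out cross-validated AUC, frozen-model cohort
    and subgroup evaluation (ROC, DeLong confidence intervals, Youden
    thresholds), single-sample gene-set enrichment (ssGSEA) scoring,
    hypergeometric pathway over-representation, Kaplan-Meier survival
    screening of per-sample scores, and a seeded negative-binomial cohort
    simulator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
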