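Package: cbdrisk
Title: Risk Stratification and Diagnostic Accuracy for Suspected Common Bile Duct Stones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three society-endorsed rule-based criteria (SAGES,
    ASGE 2019, ESGE) for stratifying patients with suspected common bile
    duct (CBD) stones into high, intermediate and low risk strata, under
    both an exclusive hierarchy and independent indicator membership.
    Evaluates stratum indicators against an ERCP gold standard with 2x2
    confusion tables, sensitivity, specificity, predictive values,
    accuracy, binary-indicator ROC/AUC with Hanley-McNeil confidence
    intervals, and Pearson chi-square association tests. Ships a
    deterministic 90-patient reconstructed reference cohort, a seeded
    synthetic-cohort simulator, CSV readers and writers for patient-level
    records, and an end-to-end evaluation pipeline with text, CSV and JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
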