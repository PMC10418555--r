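Package: panelbench
Title: Assessment of Phenotype and Causal-Variant Predictions on Gene-Panel Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring pipeline for blind prediction challenges on targeted
    gene-panel cohorts of neurodevelopmental-disorder patients. Scores
    per-trait phenotype probability submissions by MCC-optimal binarization,
    confusion-matrix metrics and bootstrap ROC/PR AUC; matches patient-specific
    predicted variants against a classified answer key (disease causing, likely
    pathogenic, contributing factor) to produce recall, precision-style
    accuracy, per-class coverage and cross-group consensus; ranks submissions
    by per-trait z-scores of AUC. A synthetic cohort generator emulates the
    cohort structure (415 patients, seven traits, 74-gene panel VCFs with
    quality-flagged decoy records) so the full assessment is reproducible
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
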