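Package: cytomil
Title: Attention-Based Multiple Instance Learning for Single-Cell
    Blood Smear Cytomorphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@cytomil.org",
           role = c("aut", "cre"))
Description: Classifies a patient's set of single white-blood-cell images
    into genetic subtypes of acute myeloid leukemia (AML) or healthy
    control using attention-based multiple instance learning with a
    class-wise attention matrix. Each patient is a "bag" of single-cell
    feature vectors; a per-class softmax attention over cells pools the
    bag into class-specific representations, so the model can both
    classify the patient and report which cells drove each class score.
    Includes quality-control filters for blood-smear image cohorts
    (Canny edge-sum blur exclusion, differential-count blast-percentage
    exclusion), a small trainable convolutional feature extractor with
    the ResNet34 recipe as configuration, patient-stratified k-fold
    cross-validation, instance-level deconvolution and attention
    concordance analyses, subsampling robustness curves, UMAP embedding
    of cell features, and a synthetic cohort generator that plants rare
    diagnostic cells among shared background so every stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    tiff,
    pROC,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
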