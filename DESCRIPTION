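Package: lesionrad
Title: Per-Lesion CT Radiomics for Chemotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-lesion CT radiomics pipeline for predicting chemotherapy
    response of individual liver metastases. Extracts a 370-feature radiomics
    vector (first-order statistics, shape, six grey-level texture-matrix
    families, and 3D stationary-wavelet sub-band features) from 3D lesion
    regions of pre-treatment CT, labels each lesion's response from
    paired-timepoint volume change using a RECIST-equivalent volume cut-off,
    and evaluates per-lesion response prediction with leave-one-patient-out
    random forests, pooled ROC/AUC with DeLong confidence intervals, Gini
    importance ranking, and feature-volume correlation auditing. Includes a
    fully seeded synthetic-cohort generator with known ground truth so every
    stage is testable without patient data.
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
    igraph,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    RNifti,
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
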