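Package: cryptmorph
Title: Quantitative 3D Morphometry of Colonic Crypts from Cleared-Tissue Fluorescence Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative three-dimensional
    histopathology of colonic mucosa imaged by carbohydrate-directed
    fluorescent staining (PAFhy-like signal) after tissue clearing.
    Provides a synthetic phantom generator with analytically known crypt
    geometry; slice-wise basement-membrane segmentation with 3D linking;
    per-crypt morphometry (volume, prolate ellipticity, centerline
    tortuosity with a 250 um depth normalization); twist-chirality
    estimation and detection of spiral staircase-like crypts; neutrophil
    gating by intensity and cell size with crypt-abscess continuity
    restriction; cohort statistics (normality-guided two-sample testing
    and Spearman rank correlation); and the data-preparation and
    evaluation layer for image-based classification (plane export,
    preprocessing, augmentation, stratified-group k-fold, confusion-matrix
    metrics and one-vs-rest AUC) with a nearest-centroid baseline
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
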