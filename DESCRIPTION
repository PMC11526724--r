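Package: dermaug
Title: Melanoma Identification from Dermoscopy Features with Ensemble
    Feature Selection and Imbalance-Aware Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying melanoma identification pipelines on
    dermoscopy-style data: synthetic lesion images and imbalanced feature
    tables with known ground truth, lesion preprocessing (resizing, hair
    removal by oriented black-hat morphology with inpainting, fallback
    segmentation), a handcrafted feature catalogue (ABCD rule, five colour
    spaces, twelve texture families including Haralick, run-length,
    size-zone, neighbourhood gray-tone difference, local binary patterns,
    wavelets and higher-order spectra), homogeneous ensemble feature
    selection with ReliefF and vote aggregation, imbalance-ratio-targeted
    SMOTE oversampling with mode-specific normalization and synthetic-data
    fidelity metrics (Hellinger distance, pairwise correlation difference,
    summed absolute PMF error, repeated-vector rate), a repeated
    cross-validated evaluation harness, and interpretability via a
    bootstrap-CI class-difference test, exact Shapley values and UMAP
    projections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    EBImage,
    mclust,
    glmnet,
    e1071,
    rpart,
    class,
    pROC,
    png
Suggests:
    testthat (>= 3.0.0),
    uwot,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
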