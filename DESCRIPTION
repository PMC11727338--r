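Package: saunet
Title: Spatial-Attention U-Net for Binary Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder convolutional network with spatial attention
    gating for binary segmentation of tumors in 2-D MRI slices, implemented
    from scratch with hand-derived backpropagation. Provides a seeded
    MRI-like phantom generator for benchmarking, a paired image/mask
    preprocessing pipeline (normalization, resizing, histogram equalization,
    denoising, geometric augmentation), binary cross-entropy training with
    patient-wise splitting, connected-component postprocessing, and a full
    evaluation suite (Dice, ROC-AUC, precision, recall, accuracy, 95th
    percentile Hausdorff distance) with multi-run aggregation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    purrr,
    tidyr,
    ggplot2,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
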