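Package: cornseed
Title: Corn Seed Defect Detection by Watershed Segmentation and a
    Two-Pathway Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end defect detection for corn (maize) seeds imaged as
    4-channel (RGB + near-infrared) multispectral scenes. Touching seeds are
    separated by marker-based watershed segmentation (Otsu binarization of the
    blue channel, morphological cleaning, distance-transform markers,
    marker-controlled flooding), each seed is resampled to a 224x224x4 chip,
    and chips are classified good/bad by a two-pathway convolutional neural
    network that fuses a VGG16-style branch with a ResNet50-style branch.
    Includes hand-crafted feature baselines (morphology, color histogram, HOG,
    GLCM, rotation-invariant uniform LBP) with an RBF-SVM classifier, macro
    precision/recall/F1 evaluation with detection-to-truth matching, and a
    synthetic scene generator with per-seed ground truth for testing the whole
    pipeline without the original imaging rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    e1071,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
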