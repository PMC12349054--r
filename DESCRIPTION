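Package: wdvessel
Title: Dual-Domain Wavelet-Deformable Network for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments retinal vasculature in fundus-style images with a
    dual-encoder U-Net that combines a Haar wavelet convolution encoder
    (frequency-domain context), a deformable convolution encoder with learned
    sampling offsets (adaptive spatial receptive fields), a gated cross-attention
    fusion bottleneck, and a depthwise-separable convolution decoder. Includes a
    complete CPU training stack (tape-based reverse-mode differentiation, Adam,
    composite binary cross-entropy plus Dice loss), the standard fundus
    preprocessing pipeline (grayscale, normalization, CLAHE, eightfold dihedral
    augmentation), pixel-wise evaluation metrics (accuracy, sensitivity,
    specificity, F1/Dice, AUC), and a seeded synthetic vascular-phantom
    generator so every component is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite,
    yaml,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
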