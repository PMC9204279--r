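Package: msfaunet
Title: Multi-Scale Fusion Attention U-Net for Thyroid Segmentation on CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation of the thyroid gland, a small organ at risk, on
    localized radiotherapy CT slices. Implements an encoder-decoder
    convolutional network that combines U-Net skip connections with
    HRNet-style parallel multi-resolution branches, repeated multi-scale
    feature fusion, and channel squeeze-and-excitation (cSE) attention
    residual blocks. Includes a complete CPU training and inference engine
    (convolution, transposed convolution, batch normalization, Adam,
    exponential learning-rate decay), the Dice loss, standard overlap and
    surface evaluation indices (DSC, JSC, PPV, SE, Hausdorff distance),
    CT preprocessing (Hounsfield conversion, window/level, contrast-limited
    adaptive histogram equalization, label-consistent augmentation),
    minimal single-frame DICOM and PNG mask input/output, patient-level
    dataset splitting, and a deterministic CT-like phantom generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
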