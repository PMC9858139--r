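Package: brainlite
Title: Lightweight CNN Classification and Fast-Linking Spiking Cortical
    Model Segmentation of Brain MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional brain magnetic-resonance image
    diagnosis: skull-stripping by a separability threshold followed by
    morphological refinement, seeded geometric data augmentation, a
    lightweight four-block convolutional neural network with exact layer
    shape and parameter accounting plus a stratified k-fold training
    harness, a fast-linking modified spiking cortical model (FL-MSCM)
    tumor segmenter with automatic parameter setting, classification and
    segmentation metrics, and a synthetic T2-like phantom generator with
    exact ground-truth masks so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    grDevices,
    graphics,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
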