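Package: pan2vol
Title: Pseudo-3D Dental Volume Reconstruction from Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs a flattened pseudo-3D dental volume from a single
    2D panoramic radiograph with an adversarially trained 2D-to-3D
    convolutional generator (least-squares GAN with voxel-wise and
    tri-plane projection regularization). Includes intensity
    preprocessing (normalization, histogram matching), sliding-window
    patch extraction and overlap-averaged reassembly, a synthetic dental
    phantom simulator with a planted impacted canine at controlled
    buccolingual and mesiodistal positions, alternating Adam training
    with 15-fold cross-validation planning, and evaluation by 3D
    structural similarity (SSIM) and automatic canine-position
    classification with confusion-table accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
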