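Package: tauseg
Title: Coarse-to-Fine Texture-Attention Segmentation of Pancreas, Tumor
    and Peripancreatic Vessels in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A coarse-to-fine framework for volumetric CT segmentation of
    the pancreas, pancreatic ductal adenocarcinoma (PDAC) and the superior
    mesenteric vessels. Provides a synthetic CT phantom generator, NIfTI
    volume handling with percentile clipping and min-max normalization,
    classic texture descriptors (rotation-invariant 2D/3D local binary
    patterns via spherical-harmonic band energies, dense SIFT), a
    sub-volume classifier for pancreas localization, attention U-Net and
    texture-attention U-Net segmentation networks with a 3D convolutional
    ensemble fuser, an imbalance-aware composite loss (weighted pixel-wise
    cross entropy, generalized Dice, differentiable boundary-F1), and
    evaluation metrics including the 95th-percentile Hausdorff distance.
    Networks are implemented on a compact CPU CNN toolkit with Rcpp
    kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
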