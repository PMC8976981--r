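Package: segxai
Title: Explainable 3D U-Net Segmentation of Multi-Parametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for explainable volumetric segmentation of
    multi-parametric prostate MRI. Provides a synthetic multi-channel
    phantom generator with dual tumor ground truths, pixelwise
    mono-exponential ADC fitting and synthetic high-b-value image
    computation, class-balanced patch sampling with rotation
    augmentation, a patch-based 3D U-Net with full reverse-mode
    gradient capture, segmentation Grad-CAM heat maps with
    mask-averaged class scores, localization-IOU and Dice evaluation of
    heat maps and segmentations, and model/cascaded randomization
    sanity checks scored by normalized mutual information and SSIM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
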