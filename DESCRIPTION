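Package: voxsr
Title: Cross-Modality Super-Resolution of 3D Volumes with Patch-Based
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying deep-learning super-resolution of volumetric
    biomedical images across imaging modalities. Simulates co-registered
    multi-modality 3D phantoms with controlled cross-modality correlation,
    down-samples them by block averaging and pre-upsamples by tricubic
    interpolation, trains patch-based 3D convolutional super-resolution
    networks (a three-layer CNN, a residual network, and a GAN) with Adam,
    Glorot initialization and early stopping, adapts trained networks to new
    contrasts by layer-frozen fine-tuning, and evaluates results with RMSE,
    3D SSIM, decorrelation-based effective resolution, paired t-tests and
    Welch's ANOVA. Includes seeded, scaled-down experiment harnesses for
    comparing network families, testing resolution matching between training
    and target data, and quantifying cross-modality transfer learning.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
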