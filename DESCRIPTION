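Package: scapseg
Title: Scapula Segmentation Networks and Glenoid Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for automatic scapular bone segmentation from
    high-resolution volumetric MRI and for clinical glenoid morphometry on the
    resulting three-dimensional bone masks. Implements configurable 2D and 3D
    V-Net encoder-decoder segmentation networks trained with a negative
    log-dice loss, deterministic preprocessing (in-plane cropping, interleaved
    slice splitting, maximum-value intensity normalization with randomized
    divisors), joint image/mask augmentation (affine, elastic, blur, noise),
    consecutive K-fold cross-validation with early stopping, and Dice-gated
    probability-averaging ensembles. A geometric scapula phantom generator
    with analytically known landmarks makes the whole pipeline testable
    without patient data. Morphometry covers glenoid height, width,
    retroversion, inclination, critical shoulder angle and RSA angle, plus
    surface-distance maps and trial-mean comparisons; the statistical module
    provides normality-gated paired tests and one-way ANOVA over Dice tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
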