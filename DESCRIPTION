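Package: bodycomp
Title: Automated CT Body-Composition Analysis at the L1 and L3 Vertebral Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for opportunistic body-composition analysis of
    thoraco-abdominal CT: heatmap-based localization of the axial slices
    intersecting the L1 and L3 vertebrae from multi-window sagittal
    projections, encoder-decoder semantic segmentation of those slices
    (trabecular/cortical bone at L1; skeletal muscle, visceral and
    subcutaneous adipose tissue at L3), and quantification of seven
    body-composition indices with the associated evaluation statistics
    (mean absolute error, Dice overlap, percentage relative error, linear
    regression and Bland-Altman agreement, k-fold cross-validation).
    Includes a compact built-in CNN engine (MultiResUNet and U-Net trained
    with Adam on CPU) and a synthetic CT phantom generator with known
    ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
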