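Package: trapdetect
Title: Small-Object Pest Detection with a Super-Resolution Feature Pyramid
    Neck and Soft-IoU Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A minimal two-stage object detector for light-trap pest
    monitoring imagery, built around two components: a multi-scale
    super-resolution feature-enhancement neck (a super-resolution pyramid
    expansion, an all-levels feature fusion stage, and a combined
    non-local/channel feature weighting stage) and a Soft-IoU overlap score
    that penalizes center displacement when assigning training samples and
    suppressing duplicate detections. Includes a seeded generator of
    synthetic light-trap scenes with COCO-format annotations, detection
    metrics (AP at fixed IoU thresholds, mean AP, mean recall), a small
    trainable CPU backbone, and a command-line interface. Convolutional
    layers and reverse-mode differentiation are implemented in-package on
    top of Rcpp kernels, so no external deep-learning framework is needed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
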