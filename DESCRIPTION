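Package: dhreg
Title: Dual-Hierarchical Patch-Based Deformable Registration of 3D Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Supervised deformable registration of 3D grayscale volumes
    (e.g. whole mouse-brain micro-optical data downsampled to atlas
    resolution) by patch-based regression of dense displacement fields.
    A dual-branch convolutional network predicts the central displacement
    block of co-located fixed/moving patches; dense fields are assembled
    by overlap-averaged sliding-window inference.  Training uses a
    self-feedback strategy that oversamples patches from high-error
    regions of the distance map, and a two-level coarse-to-fine scheme
    in which a second model learns the residual deformation left by the
    first.  Includes displacement-field algebra (warping, composition,
    Jacobian determinants), NIfTI/TIFF volume I/O, Dice and endpoint-error
    evaluation, and a synthetic phantom generator so the full pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
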