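Package: poselift
Title: Physics-Constrained Lifting of Whole-Body 2D Poses to 3D
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monocular whole-body 3D human pose estimation by 2D-to-3D
    lifting under biomechanical constraints. Provides the 133-keypoint
    whole-body skeleton model with its bone tree and part groups, an
    anthropometric centre-of-gravity engine based on moment synthesis over
    body segments, pinhole camera geometry with the constant-limb-length
    depth relation, bone-vector pose encodings, the combined position /
    centre-of-gravity / bone-consistency training objective, a dual-branch
    cross-attention Transformer lifting network implemented natively with
    analytic backpropagation, MPJPE evaluation with part grouping, and a
    synthetic paired 2D/3D pose benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
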