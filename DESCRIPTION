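Package: magnet
Title: Magnifying Networks for Weakly Supervised Classification of
    Gigapixel Image Pyramids
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end weakly supervised classification of
    multi-resolution (whole-slide style) image pyramids with recursive
    differentiable hard attention. Magnifying layers localize regions of
    interest with a spatial sparsemax, infer affine crop parameters, fetch
    each crop from a dynamically selected pyramid level, and feed the
    final patches to a recurrent classification head trained with a
    paradoxical plus cross-entropy objective. Includes a synthetic pyramid
    generator with planted multi-scale lesions, a pure reverse-mode
    autodiff core with 'Rcpp' kernels, a training loop, evaluation
    metrics, patch-trace visualization and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
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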