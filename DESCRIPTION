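Package: scutematch
Title: Individual Animal Identification from Tail-Scale Patterns by SIFT Feature Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photo-identification of individual animals from the mosaic of
    keratinized scales (scutes) on patterned body surfaces, developed for
    Eurasian beaver tails. Implements deterministic image preprocessing
    (grayscale conversion, elliptical region-of-interest extraction,
    exposure/contrast/gamma enhancement, resizing), a from-scratch
    Scale-Invariant Feature Transform (difference-of-Gaussians scale space,
    keypoint refinement, orientation assignment, 128-dimensional
    descriptors), exact k-nearest-neighbour descriptor matching with the
    ratio test, argmax identification against a labelled feature database,
    and confusion-matrix evaluation. Ships a seed-deterministic synthetic
    scale-pattern generator so the full pipeline can be benchmarked without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
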