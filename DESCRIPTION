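Package: fractensor
Title: Statistical Fractal Texture Models for Volumetric Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying 3-D gray-level image volumes by surface
    roughness. Estimates fractal dimensions of intensity surfaces by the
    blanket (covering) method and differential box counting, globally and as
    per-voxel sliding-window maps; stacks gray and fractal channels into
    order-4 feature tensors; learns a shared multilinear subspace by
    generalized N-dimensional principal component analysis (Tucker bases via
    alternating eigen-updates) with reconstruction, normalized-correlation and
    compression diagnostics plus an eigenface PCA baseline; and classifies
    core tensors with pairwise RBF support vector machines arranged as a
    directed acyclic graph, their penalty and kernel-width parameters tuned by
    ant colony optimization over a decimal-digit construction graph. Includes
    a fractional-Brownian-motion phantom generator so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
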