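Package: cytofractal
Title: Fractal and Linear Morphometry for Classifying Invertebrate Immune Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative description and unsupervised classification of
    flattened invertebrate immune cells (hemocytes) from one-bit silhouette
    images. Computes linear shape descriptors (area, perimeter, circularity,
    convex-hull and bounding-circle metrics, roundness, aspect ratio,
    symmetry ratios) and quasi-fractal descriptors (multi-grid box-counting
    and mass fractal dimensions, lacunarity, prefactor lacunarity, local and
    local-connected fractal dimensions of cell contours), screens parameters
    by a moment-based multimodality index under a correlation threshold,
    reduces dimensionality by principal-axis factoring with raw Varimax
    rotation, clusters cells by Ward's method, and evaluates candidate
    cluster solutions with Mahalanobis distances, pairwise F statistics,
    Wilks' lambda and Tukey-Kramer comparisons. Includes a seeded generator
    of synthetic cell silhouettes with planted morphotypes and analytic
    reference fractals for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
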