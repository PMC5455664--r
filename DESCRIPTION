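Package: ramanfuse
Title: Fusing Raman Spectroscopic Imaging with Micro-CT Density Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the chemical information in hyperspectral
    Raman maps to the density information in co-registered X-ray
    micro-computed-tomography (micro-CT) slices of bone samples containing
    graft substitutes. The package builds 8-bit Raman band images and
    reference-correlation maps, removes redundant layers by pairwise Pearson
    correlation, segments pixels by agglomerative hierarchical clustering
    (Euclidean distance, unweighted average linkage) with a fractional
    dendrogram cut, and quantifies the segment / gray-value relation via
    one-way ANOVA, box statistics, normalized gray-value histograms and
    coefficient-of-determination attribution. A synthetic phantom generator
    produces co-registered Raman cubes, CT slices and ground-truth labels
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
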