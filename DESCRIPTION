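Package: mtsne
Title: Structure-Preserving t-SNE for Matrix-Framed Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Embeds every element of a matrix-framed dataset (a grid of
    scalars, multivariate time series, or histograms indexed by row and
    column labels) into two dimensions while preserving both row-wise and
    column-wise group structure. The embedding minimises a convex
    combination of two Kullback-Leibler costs, one over row-margin
    affinities and one over column-margin affinities, each with its own
    perplexity-calibrated Gaussian bandwidths, and is optimised by
    momentum gradient descent. Includes dynamic time warping and
    L2-Wasserstein element distances, the classical unstructured-distance
    t-SNE baseline, cluster-separability (SSB/SST, ARI, NMI) selection of
    the row/column weight, planted-structure synthetic data generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ggplot2,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
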