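Package: imcniche
Title: Spatial Single-Cell Analysis of Multiplexed Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end spatial single-cell analysis for imaging mass
    cytometry (IMC) and similar multiplexed tissue images. Provides
    per-marker binary mask curation (median filtering, intensity-level
    quantization, blob removal, adaptive refinement), pixel-majority
    lineage assignment with a rank-priority hierarchy, fixed-radius
    cell-cell interaction and avoidance permutation tests, cellular
    neighbourhood discovery from nearest-neighbour composition windows
    via mini-batch k-means, hybrid density/spectral phenotype clustering
    with t-SNE embedding, cohort statistics with Kaplan-Meier survival
    stratification of spatial features, and a marked-point-process
    synthetic tissue generator that supplies ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    graphics,
    grDevices,
    stats,
    survival,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
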