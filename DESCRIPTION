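Package: dendriform
Title: 3D Morphometric and Topological Analysis of Elongate Dendritic Phytoliths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts geometric and topological traits from triangle surface
    meshes of Elongate dendritic phytoliths: PCA-based mesh orientation,
    voxel core-body construction by morphological opening, geodesic distance
    fields, zero-dimensional superlevel-set persistence barcodes, branching
    traits, connected-component (CC) curves, bottleneck distances and an MDS
    shape embedding (PH coordinates). Provides a hierarchical synthetic-data
    generator (branched meshes with ground truth, nested trait cohorts, trees
    with simulated traits), phylogenetic-signal statistics (Pagel's lambda
    with observation error, a multivariate K with permutation null),
    sample-level regression and LDA stages for domestication and ploidy, and
    a hierarchical Random-Forest taxonomic classification protocol with
    stratified within-sample splits, Cohen's kappa, no-information-rate
    binomial tests and Gini importances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    MASS,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
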