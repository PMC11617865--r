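Package: covnet
Title: Structural Covariance Network Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds group-level structural covariance networks (SCNs) from
    regional brain morphometry tables (cortical thickness or subcortical
    volumes in the FreeSurfer stats-table layout), removes age and
    intracranial-volume effects by per-region regression, rectifies Pearson
    correlation matrices to positive edges, thresholds them across a sparsity
    grid into binary graphs, and summarizes global and nodal graph-theoretic
    properties (clustering, path length, efficiencies, degree, betweenness)
    as areas under the curve over sparsity. Small-world indices (gamma,
    lambda, sigma) are normalized against degree-preserving rewired null
    networks. Group differences are tested by subject-shuffle permutation
    (unpaired and within-pair paired designs) with Benjamini-Hochberg FDR
    control over nodal tests, and a multivariate-normal synthetic-cohort
    generator with block correlation structure and covariate confounds
    supports power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    parallel,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
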