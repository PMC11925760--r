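Package: cbfnet
Title: Cerebral Blood Flow Covariance Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group-level covariance network analysis of regional cerebral
    blood flow (CBF). Builds across-subject Pearson correlation networks
    over atlas regions from arterial-spin-labeling style CBF maps (or
    pre-extracted regional tables), thresholds them over a proportional
    sparsity schedule into weighted or binary graphs, computes global
    graph-theoretic measures (clustering coefficient, harmonic-mean
    characteristic path length, local and global efficiency, and their
    normalizations against degree-preserving random references, including
    small-worldness), and compares groups with subject-relabeling
    permutation tests. Includes a synthetic cohort generator with
    block-modular correlation structure and covariate effects, and NIfTI
    region-of-interest extraction utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
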