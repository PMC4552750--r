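Package: regpart
Title: Regularity Partitions for Functional Brain-Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds correlation-thresholded functional-connectivity graphs from
    voxel time series and partitions them into epsilon-regular
    (pseudo-random) cluster pairs with a practical Szemeredi-type regularity
    partitioning algorithm. Provides certificate-based regularity checking of
    bipartite cluster pairs, iterative equitable refinement, partition
    descriptors (index, modularity, triangle lower bounds with sampled
    cluster triples), modified co-affinity matrices over families of
    low-modularity partitions with reverse Cuthill-McKee reordering, and a
    reduced-graph normalized-cut clustering pipeline scored by
    Hungarian-matched accuracy against ground-truth labels. Includes
    synthetic generators (stochastic block models, random bipartite graphs,
    ROI-structured voxel time series) so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr,
    Matrix
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'regpart-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'graph.R'
    'synthetic.R'
    'connectivity.R'
    'regularity.R'
    'metrics.R'
    'coaffinity.R'
    'reduction.R'
    'io.R'
    'utils.R'
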