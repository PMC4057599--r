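Package: gatewaynet
Title: Gateway Nodes in Two-State Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds hard-thresholded, significance-filtered Pearson
    correlation networks from per-state expression matrices, detects dense
    clusters with an MCODE-style k-core algorithm, integrates the retained
    clusters of two biological states into a single two-edge-type graph, and
    identifies "gateway" nodes: genes shared by a dense cluster of each state
    that bridge the two clusters. Each gateway is scored by its gatewayness,
    the fraction of cross-cluster bridging edges it carries. Includes
    Erdos-Renyi and scale-free null-network simulation for significance
    testing, lethality (essential-gene) enrichment, hypergeometric term
    enrichment, deepest-common-parent ontology edge scoring with
    depth-minus-breadth ranking of gateways, a planted-module synthetic data
    generator, and an end-to-end pipeline driver with readers and writers for
    GEO series-matrix, SIF, OBO and MGI phenotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io-series-matrix.R'
    'io-mgi.R'
    'io-obo.R'
    'io-sif.R'
    'corrnet.R'
    'mcode.R'
    'gateway.R'
    'nullmodels.R'
    'enrichment.R'
    'go-edges.R'
    'synthdata.R'
    'pipeline.R'
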