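Package: netCentral
Title: Centrality Analysis of Directed and Weighted Biological Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A suite of node, edge and network centrality indices for
    biological networks (protein-protein interaction, signalling and
    metabolic graphs): degree, eccentricity, closeness, radiality,
    centroid value, stress, betweenness, eigenvector, bridging
    centrality, edge betweenness, diameter and average distance, each
    computable on undirected, directed and weighted graphs.  Weighted
    shortest paths treat edge attributes as distances, with a
    reciprocal transform for strength-type attributes such as reaction
    speeds.  Centrality results can be joined with experimental node
    attributes (expression, phosphorylation) and classified by a
    boolean high/low-versus-threshold panel queried with conjunctions.
    Readers and writers cover SIF, edge-list TSV, GraphML and
    attribute TSV, and seeded generators produce reproducible
    benchmark and random annotated networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    graphics,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    yaml,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
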