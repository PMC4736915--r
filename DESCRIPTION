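Package: bipartmod
Title: Weighted Modularity and Module Detection in Bipartite Networks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Community detection in weighted (and binary) bipartite networks
    by maximization of Barber's bipartite modularity and its weighted
    extension. Implements the LPAwb+ label-propagation-with-agglomeration
    maximizer and the DIRTLPAwb+ restart sweep, together with the companion
    statistics used to compare partitions across networks and algorithms:
    maximum and normalized modularity, realized modularity, and normalized
    mutual information. Includes a planted-partition generator of synthetic
    modular bipartite networks with negative-binomial edge weights and a
    noise-rewiring perturbation, an evaluation harness for repeated seeded
    runs, readers and writers for incidence-matrix and edge-list files, and a
    command-line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
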