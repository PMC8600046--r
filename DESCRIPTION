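Package: peroxnet
Title: Edgetic Perturbation Analysis of the Peroxisomal Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resonance-energy-transfer (BRET) based
    protein-protein interaction screens of the peroxisomal proteome, centred
    on the membrane anchor PEX26. Turns raw dual-channel plate readings into
    binary interaction calls, assembles the merged peroxisomal interactome,
    computes the network topology measures used in interaction screening
    studies (normalized betweenness centrality, clustering, Markov
    clustering modules, node-removal robustness), builds variant-specific
    edge-loss ("edgotype") networks with hierarchical clustering of binary
    interaction profiles, scores biochemical phenotypes and correlates them
    with maintained interactions, and integrates gene-phenotype
    associations into a heterogeneous protein-disease network. Includes a
    synthetic plate-reading generator with known ground truth so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    igraph,
    Matrix,
    methods,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ape,
    withr
Config/testthat/edition: 3
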