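Package: netpertr
Title: Perturbation-Theory Ranking of Intermediate Genes in Driver-Response Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks intermediate vertices of a mixed protein-protein
    interaction / gene-regulatory network by how strongly a small
    perturbation of each vertex changes the signaling response from a
    driver gene to a set of response genes. The response function is the
    matrix exponential of the unnormalized graph Laplacian dynamics; the
    per-vertex weight is a first-order sensitivity obtained by convolving
    two Green's functions. Includes two comparison methods (subset
    betweenness centrality and tied graph diffusion linking scores),
    short-time analytic limits, drug-assay evaluation by Spearman rank
    correlation within gene groups, and seeded synthetic networks with
    finite-difference oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
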