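Package: seednet
Title: Single-Gene Network Expansion by Iterated PC-Skeleton Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs gene association networks from a normalized
    expression compendium by expanding one seed gene at a time: the gene
    universe is repeatedly tiled into random seed-containing subsets, the
    undirected skeleton of a causal graph is estimated on each subset with
    the order-independent (stable) PC algorithm and Fisher-z partial
    correlation tests, and the fraction of runs in which a gene stays
    adjacent to the seed (its relative frequency) ranks candidate direct
    interactions. Includes tools to combine per-seed expansion lists into
    networks by mutual presence, to aggregate lists into candidate tables by
    relative frequency, rank, functional category or sharing, GO
    over-representation analysis with true-path propagation, strand-aware
    promoter extraction for motif discovery, and a linear-Gaussian
    structural-equation simulator with known ground truth for benchmarking
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    parallel,
    grDevices,
    graphics,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
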