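Package: egtcensus
Title: Census of Endosymbiotic Gene Transfer in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects organelle-derived insertions (NUPTs and NUMTs) in nuclear
    genomes with a seed-chain-extend detector, summarises them as exchange
    rates, size-class histograms and copy-number profiles, classifies nuclear
    genes as cyanobacterial recruits from gene trees, qualifies expression from
    EST evidence, performs GO term-abundance analysis with GO-Slim mapping and
    hypergeometric tests, lays out term fingerprints as weight-proportional
    Voronoi treemaps, and computes group-level genome statistics. Ships seeded
    synthetic-data generators with exact ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    igraph,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
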