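Package: dcjhalving
Title: DCJ-Indel Genome Halving for Natural Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome halving problem under the double-cut-and-join
    (DCJ) model with segmental insertions and deletions. Computes the exact
    restricted DCJ-indel halving distance in polynomial time for genomes with
    resolved homology (every gene family of size at most two), produces an
    optimal sorting scenario together with the reconstructed structurally
    doubled ancestor, and solves the general problem for natural genomes
    (arbitrary family sizes) under the maximum-matching model with a
    capping-free integer linear program. Includes a supernatural-graph
    component census (cycles, viaducts, piers, pontoons), a whole-genome
    duplication evolution simulator with Zipf-distributed indel and
    duplication lengths, brute-force reference oracles for validation, and
    readers and writers for UniMoG-style gene-order files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with scipy >= 1.9 (HiGHS MILP backend)
Config/testthat/edition: 3
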