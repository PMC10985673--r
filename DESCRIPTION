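Package: lshtax
Title: Taxonomic Classification and Profiling of Metagenomic Reads via
    Locality-Sensitive k-mer Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies short metagenomic reads and estimates per-rank
    taxonomic abundance profiles using bit-sampling locality-sensitive
    hashing (LSH) of 2-bit-packed 32-mers. Reference k-mers are stored in
    fixed-size bucketed hash tables supporting approximate
    nearest-neighbour search under Hamming distance; each stored k-mer
    carries a probabilistic soft lowest-common-ancestor (LCA) taxon label.
    Reads are classified by distance-weighted voting aggregated bottom-up
    over the taxonomy with a majority-vote rank-selection rule, and samples
    are profiled with a two-level normalization scheme including an
    explicit unclassified component and optional genome-size correction.
    Includes a seeded synthetic-world generator (taxonomy, evolved
    reference genomes, error-bearing reads at controlled novelty) so the
    whole pipeline is testable without external data, per-rank
    precision/recall/F1 evaluation, profile quality metrics (Bray-Curtis
    dissimilarity, Shannon's equitability, L1 norm), and a subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
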