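# Shared fixtures and independent string-level oracles.

BASES4 <- c("A", "C", "G", "T")

random_kmer_strings <- function(n, k = 32) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES4, k, replace = TRUE), collapse = ""), "")
}

# oracle: reverse complement by character operations
str_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# oracle: character-wise Hamming distance
str_hd <- function(a, b) {
  mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b,
    USE.NAMES = FALSE)
}

# mutate exactly d positions of a k-mer string (each to a different base)
mutate_exact <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  at <- sample(length(ch), d)
  for (i in at) ch[i] <- sample(setdiff(BASES4, ch[i]), 1)
  paste(ch, collapse = "")
}

# 17-node hand-built taxonomy:
#   root - sk1 - {p1 - c1 - o1 - f1 - {g1 - {s1, s3}, g2 - s2},
#                 p2 - c2 - o2 - f2 - g3 - s4}
fixture_tree <- function() {
  nodes <- data.frame(
    taxid  = 1:17,
    parent_taxid = c(0, 1, 2, 2, 3, 5, 6, 7, 7, 8, 9, 8, 4, 13, 14, 15, 16),
    rank = c("no rank", "superkingdom", "phylum", "phylum", "class",
             "order", "family", "genus", "genus", "species", "species",
             "species", "class", "order", "family", "genus", "species"),
    name = c("root", "sk1", "p1", "p2", "c1", "o1", "f1", "g1", "g2",
             "s1", "s2", "s3", "c2", "o2", "f2", "g3", "s4"),
    stringsAsFactors = FALSE)
  taxonomy(nodes)
}

fx_id <- function(tree, name) taxon_by_name(tree, name)

# vote table from a named direct-vote vector (names = node names)
make_vote_table <- function(tree, direct_named) {
  direct <- numeric(nrow(tree$nodes))
  direct[taxon_by_name(tree, names(direct_named))] <- direct_named
  total <- lshtax:::aggregate_votes(direct, tree)
  structure(list(direct = direct, total = total,
                 root_total = total[tree$root]),
            class = "vote_table")
}

# tiny deterministic world for pipeline tests
small_world <- function(seed = 7, genome_length = 20000,
                        reads_per_query = 200) {
  generate_world(synth_config(seed = seed, genome_length = genome_length,
                              reads_per_query = reads_per_query))
}

small_params <- function(h = 9) lsh_params(h = h, b = 7, l = 2)
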