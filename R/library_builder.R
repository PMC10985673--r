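#' @title Reference library construction with probabilistic soft-LCA labels
#' @name library_builder
#' @description Building a library is three passes over the reference
#'   genomes: (1) canonical k-mers are inserted into the LSH index, (2) the
#'   genome-occurrence count Ni of every stored k-mer is tallied, (3) for
#'   each genome g and each of its stored k-mers, a coin with success
#'   probability `p_update(Ni)` decides whether the k-mer's label moves to
#'   `LCA(label, species(g))`. Coins are derived deterministically from
#'   (seed, k-mer, genome id), so labels do not depend on genome order.
NULL

#' Soft-LCA parameters
#' @param w decrease-rate parameter of the update probability (default 4).
#' @param s offset parameter: k-mers in at most `s` genomes are always
#'   labeled (default 5).
#' @param seed seed for the per-(k-mer, genome) update coins.
#' @return an object of class `soft_lca_params`.
#' @export
soft_lca_params <- function(w = 4, s = 5, seed = 1) {
  stopifnot(w >= 1, s >= 1)
  structure(list(w = w, s = s, seed = as.integer(seed)),
            class = "soft_lca_params")
}

#' Label update probability
#'
#' `p_update(Ni) = min(w / max(Ni + w - s, w) + 1/s^2, 1)`: equal to 1 for
#' rare k-mers (`Ni <= s`), non-increasing in Ni, tending to `1/s^2` so
#' even ubiquitous k-mers keep a nonzero chance of carrying a label.
#'
#' @param Ni number of genomes containing the k-mer (vectorized, `>= 1`).
#' @param w,s soft-LCA parameters (defaults 4 and 5).
#' @return update probabilities in `(0, 1]`.
#' @export
p_update <- function(Ni, w = 4, s = 5) {
  stopifnot(all(Ni >= 1))
  pmin(w / pmax(Ni + w - s, w) + 1 / s^2, 1)
}

# normalize the many accepted genome representations to a named list of
# contig character vectors
as_genome_set <- function(genomes) {
  if (is.data.frame(genomes)) {
    stopifnot(all(c("genome_id", "path") %in% names(genomes)))
    out <- lapply(seq_len(nrow(genomes)), function(i) {
      p <- genomes$path[i]
      if (!file.exists(p)) stop("cannot read FASTA for genome '",
                                genomes$genome_id[i], "': ", p)
      unname(read_sequences(p))
    })
    names(out) <- genomes$genome_id
    return(out)
  }
  if (is.character(genomes)) genomes <- as.list(genomes)
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  genomes
}

genome_kmers <- function(contigs, params, minimizer_window = NULL) {
  reads_to_kmer_stream(contigs, k = params$k,
                       minimizer_window = minimizer_window)$kmers
}

#' Count genome occurrences Ni of stored k-mers
#'
#' For each stored k-mer, Ni is the number of distinct genomes containing
#' it (repeats within one genome count once). Run after all insertions.
#'
#' @param index an [lsh_index()] with reference k-mers inserted.
#' @param genomes named list/vector of genome sequences, or a data.frame
#'   with `genome_id` and `path` (FASTA) columns.
#' @param minimizer_window optional minimizer window (see
#'   [read_to_kmers()]); must match the insertion pass.
#' @return the index, invisibly (counts live in the index).
#' @export
count_genome_occurrences <- function(index, genomes,
                                     minimizer_window = NULL) {
  gs <- as_genome_set(genomes)
  for (g in gs) {
    km <- genome_kmers(g, index$params, minimizer_window)
    cpp_index_count_genome(index$ptr, km$hi, km$lo)
  }
  invisible(index)
}

#' Assign probabilistic soft-LCA labels
#'
#' @param index an [lsh_index()] with counts computed.
#' @param genomes as in [count_genome_occurrences()].
#' @param tree a [taxonomy] whose `genomes` table maps every genome id to
#'   its species taxon.
#' @param params a [soft_lca_params()].
#' @param minimizer_window as in [count_genome_occurrences()].
#' @return the index, invisibly (labels live in the index).
#' @export
assign_soft_lca <- function(index, genomes, tree,
                            params = soft_lca_params(),
                            minimizer_window = NULL) {
  gs <- as_genome_set(genomes)
  species <- tree$genomes$taxon[match(names(gs), tree$genomes$genome_id)]
  if (anyNA(species))
    stop("genome(s) missing from the taxonomy: ",
         paste(names(gs)[is.na(species)], collapse = ", "))
  for (i in seq_along(gs)) {
    km <- genome_kmers(gs[[i]], index$params, minimizer_window)
    cpp_index_soft_lca_genome(index$ptr, km$hi, km$lo, species[i],
                              tree$nodes$parent, params$w, params$s,
                              params$seed, names(gs)[i])
  }
  invisible(index)
}

#' Build a labeled reference library
#'
#' Runs insertion, Ni counting, and soft-LCA labeling, seeding all
#' randomness (hash positions, bucket reservoirs, label coins) from
#' `seed`. With a fixed genome order the result is fully deterministic;
#' labels are additionally order-invariant by construction.
#'
#' @param genomes as in [count_genome_occurrences()].
#' @param tree a [taxonomy] with all genomes attached at species taxa.
#' @param params an [lsh_params()].
#' @param lca_params a [soft_lca_params()]; its seed is overridden by
#'   `seed`.
#' @param seed master seed.
#' @param minimizer_window optional minimizer window.
#' @return an [lsh_index()] with labels and counts populated.
#' @export
build_library <- function(genomes, tree, params = lsh_params(),
                          lca_params = soft_lca_params(), seed = 1,
                          minimizer_window = NULL) {
  gs <- as_genome_set(genomes)
  missing <- setdiff(names(gs), tree$genomes$genome_id)
  if (length(missing))
    stop("genome(s) missing from the taxonomy: ",
         paste(missing, collapse = ", "))
  index <- lsh_index(params, seed = seed)
  withr_seed(seed, {
    for (g in gs) {
      km <- genome_kmers(g, params, minimizer_window)
      lsh_insert(index, km)
    }
  })
  count_genome_occurrences(index, gs, minimizer_window)
  lca_params$seed <- as.integer(seed)
  assign_soft_lca(index, gs, tree, lca_params, minimizer_window)
  index
}

#' Library build report
#'
#' @param index a built [lsh_index()].
#' @param tree the [taxonomy] used for labeling.
#' @return list with the stored k-mer count, a label tally by rank
#'   (including `"unassigned"`), and the Ni histogram.
#' @export
build_report <- function(index, tree) {
  labels <- index_labels(index)
  counts <- index_counts(index)
  rank <- ifelse(labels == 0, "unassigned", tree$nodes$rank[labels])
  list(n_kmers = index_size(index),
       labels_by_rank = table(rank),
       ni_histogram = table(counts))
}
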