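#' @title Synthetic test worlds
#' @name synthgen
#' @description Generates a fully seeded world: a small taxonomy over the
#'   seven canonical ranks, reference genomes evolved along it by i.i.d.
#'   substitutions (Jukes-Cantor style, no indels, keeping the Hamming
#'   model exact), and query reads drawn from a genome mutated away from
#'   its donor at a controlled normalized distance — the novelty axis —
#'   with i.i.d. substitution sequencing errors.
NULL

#' Synthetic world configuration
#'
#' Defaults describe a desk-scale world: 24 reference genomes of 100 kb
#' (1 superkingdom x 2 phyla x 2 families x 2 genera x 3 species, with
#' single-child class and order levels), 5% expected substitutions per
#' site per tree level, 150 bp reads, 2000 reads per query, and a 0.5%
#' per-base sequencing error rate.
#'
#' @param seed master seed.
#' @param branching named integer vector of children per node at each
#'   rank, highest first; names must be canonical ranks.
#' @param genome_length reference genome length in bases.
#' @param divergence expected substitutions per site accumulated along
#'   each tree level (scalar or one value per rank), in `[0, 0.75)`.
#' @param read_length read length L.
#' @param reads_per_query reads generated per query genome.
#' @param error_rate per-base sequencing substitution error rate.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 42,
                         branching = c(superkingdom = 1, phylum = 2,
                                       class = 1, order = 1, family = 2,
                                       genus = 2, species = 3),
                         genome_length = 100000,
                         divergence = 0.05,
                         read_length = 150,
                         reads_per_query = 2000,
                         error_rate = 0.005) {
  stopifnot(all(names(branching) %in% CANONICAL_RANKS),
            all(divergence >= 0), all(divergence < 0.75),
            genome_length >= read_length)
  divergence <- rep_len(divergence, length(branching))
  names(divergence) <- names(branching)
  structure(list(seed = as.integer(seed), branching = branching,
                 genome_length = as.integer(genome_length),
                 divergence = divergence,
                 read_length = as.integer(read_length),
                 reads_per_query = as.integer(reads_per_query),
                 error_rate = error_rate),
            class = "synth_config")
}

BASES <- c("A", "C", "G", "T")

# substitute each position independently with probability `rate`, drawing
# uniformly among the three alternative bases
mutate_sequence <- function(seq_chars, rate) {
  if (rate <= 0) return(seq_chars)
  hit <- which(runif(length(seq_chars)) < rate)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    old <- match(seq_chars[hit], BASES) - 1L
    seq_chars[hit] <- BASES[((old + shift) %% 4L) + 1L]
  }
  seq_chars
}

#' Generate a synthetic world
#'
#' Draws a uniform-ACGT root genome and evolves one genome per taxonomy
#' node by mutating its parent at the configured per-level rate; leaves
#' (species) keep their genomes as the reference set, one genome per
#' species. Deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_world`: `tree` (a [taxonomy] with genomes
#'   attached), `genomes` (named character vector of reference sequences),
#'   `config`.
#' @export
generate_world <- function(config = synth_config()) {
  withr_seed(config$seed, {
    ranks <- names(config$branching)
    root_seq <- sample(BASES, config$genome_length, replace = TRUE)
    nodes <- data.frame(taxid = 1L, parent_taxid = 0L, rank = "no rank",
                        name = "root", stringsAsFactors = FALSE)
    seqs <- list("1" = root_seq)
    frontier <- 1L
    next_id <- 2L
    for (li in seq_along(ranks)) {
      new_frontier <- integer(0)
      for (parent in frontier) {
        for (ci in seq_len(config$branching[[li]])) {
          tid <- next_id
          next_id <- next_id + 1L
          nodes <- rbind(nodes, data.frame(
            taxid = tid, parent_taxid = parent, rank = ranks[li],
            name = sprintf("%s_%d", substr(ranks[li], 1, 3), tid),
            stringsAsFactors = FALSE))
          seqs[[as.character(tid)]] <-
            mutate_sequence(seqs[[as.character(parent)]],
                            config$divergence[[li]])
          new_frontier <- c(new_frontier, tid)
        }
      }
      frontier <- new_frontier
    }
    tree <- taxonomy(nodes)
    species_taxids <- nodes$taxid[nodes$rank == "species"]
    genomes <- vapply(as.character(species_taxids),
                      function(tid) paste(seqs[[tid]], collapse = ""), "")
    names(genomes) <- sprintf("G_%s",
                              nodes$name[match(species_taxids, nodes$taxid)])
    gt <- setNames(match(species_taxids, tree$nodes$taxid), names(genomes))
    tree <- set_genomes(tree, gt, setNames(nchar(genomes), names(genomes)))
    structure(list(tree = tree, genomes = genomes, config = config),
              class = "synth_world")
  })
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> %d reference genome(s) of %d bases, %d taxa\n",
              length(x$genomes), x$config$genome_length, nrow(x$tree$nodes)))
  invisible(x)
}

#' Write a world to disk
#'
#' Emits one FASTA per reference genome, a `reference_list.tsv`
#' (genome_id, taxid, path), a lineage TSV, and the taxonomy TSV.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- world$tree
  paths <- character(length(world$genomes))
  for (i in seq_along(world$genomes)) {
    gid <- names(world$genomes)[i]
    paths[i] <- file.path(dir, paste0(gid, ".fasta"))
    write_sequences(setNames(world$genomes[i], gid), paths[i])
  }
  ref <- data.frame(genome_id = names(world$genomes),
                    taxid = tree$nodes$taxid[tree$genomes$taxon[
                      match(names(world$genomes), tree$genomes$genome_id)]],
                    path = basename(paths))  # relative to the list's dir
  write.table(ref, file.path(dir, "reference_list.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_taxonomy(tree, file.path(dir, "taxonomy.tsv"))
  lin <- lapply(names(world$genomes), function(gid) {
    sp <- tree$genomes$taxon[match(gid, tree$genomes$genome_id)]
    lintax <- vapply(CANONICAL_RANKS,
                     function(r) {
                       a <- rank_of_lineage(tree, sp, r)
                       if (is.na(a)) "" else tree$nodes$name[a]
                     }, "")
    c(genome_id = gid, lintax)
  })
  lin <- as.data.frame(do.call(rbind, lin), stringsAsFactors = FALSE)
  write.table(lin, file.path(dir, "lineages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a query read set at controlled novelty
#'
#' A donor reference genome is mutated at per-site rate `novelty` to form
#' the query genome (its distance to the nearest reference is then
#' approximately `novelty`), and reads are uniform substrings from either
#' strand with i.i.d. substitution errors. The truth table records the
#' donor's lineage and the realized genome distance.
#'
#' @param world a [generate_world()] result.
#' @param novelty target normalized distance in `[0, 0.75)` to the donor.
#' @param n_reads number of reads (default from the world config).
#' @param read_length read length (default from the config).
#' @param error_rate per-base sequencing error rate (default from the
#'   config).
#' @param seed seed for mutation, sampling and errors.
#' @param donor genome id to mutate (default: seeded random choice).
#' @return list of class `synth_queries`: `reads` (named character
#'   vector), `truth` (data.frame: read_id, genome_id, taxon, rank ...,
#'   realized_distance), `query_genome`.
#' @export
generate_queries <- function(world, novelty = 0,
                             n_reads = world$config$reads_per_query,
                             read_length = world$config$read_length,
                             error_rate = world$config$error_rate,
                             seed = world$config$seed + 1,
                             donor = NULL) {
  if (novelty < 0 || novelty >= 0.75)
    stop("novelty must be in [0, 0.75)")
  withr_seed(seed, {
    if (is.null(donor)) donor <- sample(names(world$genomes), 1)
    stopifnot(donor %in% names(world$genomes))
    donor_seq <- strsplit(world$genomes[[donor]], "")[[1]]
    query_seq <- mutate_sequence(donor_seq, novelty)
    realized <- mean(query_seq != donor_seq)
    glen <- length(query_seq)
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
    revflag <- runif(n_reads) < 0.5
    reads <- vapply(seq_len(n_reads), function(i) {
      r <- query_seq[starts[i]:(starts[i] + read_length - 1L)]
      r <- mutate_sequence(r, error_rate)
      paste(r, collapse = "")
    }, "")
    long <- which(revflag)
    if (length(long)) reads[long] <- reverse_complement_long(reads[long])
    names(reads) <- sprintf("q%05d", seq_len(n_reads))
    sp <- world$tree$genomes$taxon[
      match(donor, world$tree$genomes$genome_id)]
    truth <- data.frame(read_id = names(reads), genome_id = donor,
                        taxon = sp, realized_distance = realized,
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth,
                   query_genome = paste(query_seq, collapse = ""),
                   novelty = novelty, donor = donor),
              class = "synth_queries")
  })
}

# reverse complement for arbitrary-length strings (reads exceed 32 bases,
# so the packed-codec path does not apply)
reverse_complement_long <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(seqs, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}
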