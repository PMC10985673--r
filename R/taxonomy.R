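#' @title Rank-annotated taxonomy
#' @name taxonomy
#' @description A single-rooted tree over at most 65,535 taxa (internal ids
#'   fit 2 bytes; id 0 is reserved for "unassigned" k-mer labels). Ranks
#'   follow the seven canonical levels from species up to superkingdom;
#'   non-canonical levels are carried as "no rank" pass-through nodes that
#'   lineage projection skips. Reference genomes attach at species-level
#'   taxa and contribute their lengths to per-clade mean genome lengths.
NULL

#' Canonical rank order, lowest (species) to highest (superkingdom)
#' @export
CANONICAL_RANKS <- c("species", "genus", "family", "order", "class",
                     "phylum", "superkingdom")

#' Build a taxonomy from a node table
#'
#' @param nodes data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   and optionally `name`. The root is the node whose parent is itself, 0
#'   or NA. Internal 2-byte ids are assigned in sorted-taxid order.
#' @return an object of class `taxonomy`.
#' @export
taxonomy <- function(nodes) {
  stopifnot(all(c("taxid", "parent_taxid", "rank") %in% names(nodes)))
  if (nrow(nodes) > 65535L)
    stop("taxonomy has ", nrow(nodes), " taxa; at most 65535 supported")
  if (anyDuplicated(nodes$taxid)) stop("duplicated taxid in node table")
  nodes <- nodes[order(nodes$taxid), , drop = FALSE]
  n <- nrow(nodes)
  id <- seq_len(n)
  is_root <- is.na(nodes$parent_taxid) | nodes$parent_taxid == 0 |
    nodes$parent_taxid == nodes$taxid
  if (sum(is_root) != 1)
    stop("taxonomy must have exactly one root, found ", sum(is_root))
  parent <- match(nodes$parent_taxid, nodes$taxid)
  parent[is_root] <- 0L
  if (anyNA(parent)) stop("unknown parent taxid: ",
                          nodes$parent_taxid[is.na(parent)][1])
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  frontier <- id[is_root]
  while (length(frontier)) {
    children <- id[parent %in% frontier & is.na(depth)]
    depth[children] <- depth[match(parent[children], id)] + 1L
    frontier <- children
  }
  if (anyNA(depth)) stop("taxonomy contains a cycle or unreachable nodes")
  rank <- as.character(nodes$rank)
  ri <- match(rank, CANONICAL_RANKS)  # NA for "no rank" etc.
  for (i in id[!is.na(ri)]) {
    a <- parent[i]
    while (a != 0 && is.na(ri[a])) a <- parent[a]
    if (a != 0 && ri[a] <= ri[i])
      stop("rank order violated: ", rank[i], " under ", rank[a])
  }
  structure(list(
    nodes = data.frame(
      id = id, taxid = nodes$taxid, parent = parent, rank = rank,
      name = if ("name" %in% names(nodes)) as.character(nodes$name)
             else as.character(nodes$taxid),
      stringsAsFactors = FALSE),
    rank_index = ri,
    depth = depth,
    root = id[is_root],
    agg_order = id[order(depth, decreasing = TRUE)],
    ranks = CANONICAL_RANKS,
    genomes = data.frame(genome_id = character(), taxon = integer(),
                         length = numeric(), stringsAsFactors = FALSE)
  ), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d taxa, %d genome(s), root '%s'\n",
              nrow(x$nodes), nrow(x$genomes), x$nodes$name[x$root]))
  invisible(x)
}

n_taxa <- function(tree) nrow(tree$nodes)

#' Attach reference genomes to species-level taxa
#'
#' @param tree a [taxonomy].
#' @param genome_taxon named integer vector: genome id -> internal taxon id
#'   (must be species-rank nodes).
#' @param genome_length named numeric vector of genome lengths in bases
#'   (same names; optional, NA allowed).
#' @return the updated tree.
#' @export
set_genomes <- function(tree, genome_taxon, genome_length = NULL) {
  stopifnot(!is.null(names(genome_taxon)))
  bad <- genome_taxon[is.na(tree$rank_index[genome_taxon]) |
                      tree$nodes$rank[genome_taxon] != "species"]
  if (length(bad))
    stop("genomes must attach at species-rank taxa; offending taxon id(s): ",
         paste(unique(bad), collapse = ", "))
  len <- rep(NA_real_, length(genome_taxon))
  if (!is.null(genome_length))
    len <- as.numeric(genome_length[names(genome_taxon)])
  tree$genomes <- data.frame(genome_id = names(genome_taxon),
                             taxon = as.integer(genome_taxon),
                             length = len, stringsAsFactors = FALSE)
  tree
}

#' Lowest common ancestor
#' @param tree a [taxonomy].
#' @param a,b internal taxon ids (scalars).
#' @return internal id of the deepest common ancestor.
#' @export
lca <- function(tree, a, b) {
  check_taxon(tree, c(a, b))
  parent <- tree$nodes$parent
  depth <- tree$depth
  while (depth[a] > depth[b]) a <- parent[a]
  while (depth[b] > depth[a]) b <- parent[b]
  while (a != b) { a <- parent[a]; b <- parent[b] }
  a
}

#' LCA of a set of taxa
#' @param tree a [taxonomy].
#' @param taxa integer vector of internal ids (non-empty).
#' @return internal id.
#' @export
lca_set <- function(tree, taxa) Reduce(function(a, b) lca(tree, a, b), taxa)

check_taxon <- function(tree, t) {
  if (any(is.na(t)) || any(t < 1) || any(t > n_taxa(tree)))
    stop("unknown taxon id: ", paste(t[is.na(t) | t < 1 | t > n_taxa(tree)],
                                     collapse = ", "))
  invisible(t)
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage of `t` upward and returns its ancestor-or-self at rank
#' `rank`, or `NA` when `t` sits above that rank or the rank is absent from
#' the lineage ("no rank" pass-through nodes are skipped).
#'
#' @param tree a [taxonomy].
#' @param t internal taxon id (scalar).
#' @param rank one of [CANONICAL_RANKS].
#' @return internal id or `NA_integer_`.
#' @export
rank_of_lineage <- function(tree, t, rank) {
  check_taxon(tree, t)
  target <- match(rank, tree$ranks)
  if (is.na(target)) stop("unknown rank: ", rank)
  a <- t
  while (a != 0) {
    ri <- tree$rank_index[a]
    if (!is.na(ri)) {
      if (ri == target) return(a)
      if (ri > target) return(NA_integer_)  # t (or lineage) is above rank
    }
    a <- tree$nodes$parent[a]
  }
  NA_integer_
}

#' Children of a taxon
#' @param tree a [taxonomy].
#' @param t internal taxon id.
#' @return integer vector of child ids.
#' @export
taxon_children <- function(tree, t) {
  check_taxon(tree, t)
  tree$nodes$id[tree$nodes$parent == t]
}

#' Look up taxa by name
#' @param tree a [taxonomy].
#' @param name character vector of node names.
#' @return internal ids (NA where absent).
#' @export
taxon_by_name <- function(tree, name) match(name, tree$nodes$name)

#' All internal ids at a rank
#' @param tree a [taxonomy].
#' @param rank one of [CANONICAL_RANKS].
#' @return integer vector.
#' @export
taxa_at_rank <- function(tree, rank) {
  tree$nodes$id[!is.na(tree$rank_index) &
                tree$nodes$rank == rank]
}

#' Taxa at a rank represented by at least one reference genome
#' @param tree a [taxonomy] with genomes attached.
#' @param rank one of [CANONICAL_RANKS].
#' @return integer vector of internal ids.
#' @export
reference_taxa <- function(tree, rank) {
  anc <- vapply(unique(tree$genomes$taxon),
                function(t) rank_of_lineage(tree, t, rank), integer(1))
  sort(unique(anc[!is.na(anc)]))
}

#' Per-taxon mean reference genome length
#'
#' `l_t` of a taxon is the mean length of all reference genomes in its
#' clade; the root's value equals the global mean.
#'
#' @param tree a [taxonomy] with genomes (and lengths) attached.
#' @return numeric vector indexed by internal id (NA for clades without
#'   genomes).
#' @export
taxon_genome_lengths <- function(tree) {
  n <- n_taxa(tree)
  tot <- numeric(n)
  cnt <- integer(n)
  for (i in seq_len(nrow(tree$genomes))) {
    len <- tree$genomes$length[i]
    if (is.na(len)) next
    a <- tree$genomes$taxon[i]
    while (a != 0) {
      tot[a] <- tot[a] + len
      cnt[a] <- cnt[a] + 1L
      a <- tree$nodes$parent[a]
    }
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Parse an NCBI-style taxonomy dump
#'
#' Reads the `nodes.dmp` field layout (pipe-delimited: taxid, parent taxid,
#' rank, ...) and optionally `names.dmp` (taxid, name, unique name, name
#' class; scientific names are used).
#'
#' @param nodes_path path to a nodes.dmp-style file.
#' @param names_path optional path to a names.dmp-style file.
#' @return a [taxonomy].
#' @export
parse_ncbi_dump <- function(nodes_path, names_path = NULL) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t?\\|$", "", lines)
    do.call(rbind, strsplit(lines, "\t\\|\t"))
  }
  nd <- parse_dmp(nodes_path)
  nodes <- data.frame(taxid = as.integer(nd[, 1]),
                      parent_taxid = as.integer(nd[, 2]),
                      rank = trimws(nd[, 3]), stringsAsFactors = FALSE)
  if (!is.null(names_path)) {
    nm <- parse_dmp(names_path)
    sci <- nm[trimws(nm[, 4]) == "scientific name", , drop = FALSE]
    nodes$name <- trimws(sci[match(nodes$taxid, as.integer(sci[, 1])), 2])
  }
  taxonomy(nodes)
}

#' Parse a genome lineage TSV into a taxonomy
#'
#' The TSV has a `genome_id` column plus one column per canonical rank
#' (any subset, in any order); cells are taxon names, empty for missing
#' ranks. The `species` column is mandatory. Synthetic taxids are assigned
#' deterministically (breadth-first over sorted names), and genomes attach
#' at their species.
#'
#' @param path TSV file path.
#' @param genome_length optional named numeric vector of genome lengths.
#' @return a [taxonomy] with genomes attached.
#' @export
parse_lineage_tsv <- function(path, genome_length = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lineages_to_taxonomy(df, genome_length)
}

#' @rdname parse_lineage_tsv
#' @param lineages data.frame as described for `parse_lineage_tsv`.
#' @export
lineages_to_taxonomy <- function(lineages, genome_length = NULL) {
  stopifnot("genome_id" %in% names(lineages), "species" %in% names(lineages))
  rank_cols <- intersect(rev(CANONICAL_RANKS), names(lineages))  # high->low
  if (any(is.na(lineages$species) | lineages$species == ""))
    stop("every genome needs a species name")
  paths <- list()
  for (i in seq_len(nrow(lineages))) {
    lin <- character(0)
    for (rc in rank_cols) {
      v <- lineages[[rc]][i]
      if (!is.na(v) && nzchar(v)) lin[rc] <- v
    }
    paths[[i]] <- lin
  }
  # enumerate unique nodes breadth-first in sorted-name order
  node_key <- character(0)   # full path key
  node_rank <- character(0)
  node_name <- character(0)
  node_parent_key <- character(0)
  for (d in seq_along(rank_cols)) {
    keys <- unique(unlist(lapply(paths, function(lin) {
      if (length(lin) < d) return(NULL)
      paste(lin[seq_len(d)], collapse = "/")
    })))
    for (key in sort(keys)) {
      node_key <- c(node_key, key)
      parts <- strsplit(key, "/", fixed = TRUE)[[1]]
      node_name <- c(node_name, parts[length(parts)])
      node_parent_key <- c(node_parent_key,
                           if (d == 1) "" else
                             paste(parts[-length(parts)], collapse = "/"))
      # rank of this node: the d-th rank present for any genome with this
      # prefix; lineages sharing a prefix share rank structure by column
      lin1 <- paths[[which(vapply(paths, function(lin)
        length(lin) >= d &&
          paste(lin[seq_len(d)], collapse = "/") == key, TRUE))[1]]]
      node_rank <- c(node_rank, names(lin1)[d])
    }
  }
  nodes <- data.frame(
    taxid = seq_along(node_key) + 1L,
    parent_taxid = ifelse(node_parent_key == "", 1L,
                          match(node_parent_key, node_key) + 1L),
    rank = node_rank, name = node_name, stringsAsFactors = FALSE)
  nodes <- rbind(data.frame(taxid = 1L, parent_taxid = 0L, rank = "no rank",
                            name = "root", stringsAsFactors = FALSE), nodes)
  tree <- taxonomy(nodes)
  species_key <- vapply(paths, function(lin)
    paste(lin, collapse = "/"), "")
  gt <- setNames(taxon_by_name_key(tree, node_key, species_key),
                 lineages$genome_id)
  set_genomes(tree, gt, genome_length)
}

# map full path keys to internal ids (node taxids are key position + 1)
taxon_by_name_key <- function(tree, node_key, keys) {
  taxid <- match(keys, node_key) + 1L
  match(taxid, tree$nodes$taxid)
}

#' Write / read a taxonomy as TSV
#'
#' `write_taxonomy` emits a nodes table (`taxid`, `parent_taxid`, `rank`,
#' `name`) and, when genomes are attached, a companion
#' `<path>.genomes.tsv` (`genome_id`, `taxid`, `length`). `read_taxonomy`
#' reverses it.
#'
#' @param tree a [taxonomy].
#' @param path output TSV path.
#' @return `write_taxonomy`: `path`, invisibly; `read_taxonomy`: a
#'   [taxonomy].
#' @export
write_taxonomy <- function(tree, path) {
  pt <- integer(nrow(tree$nodes))
  has_parent <- tree$nodes$parent != 0
  pt[has_parent] <- tree$nodes$taxid[tree$nodes$parent[has_parent]]
  out <- data.frame(taxid = tree$nodes$taxid, parent_taxid = pt,
                    rank = tree$nodes$rank, name = tree$nodes$name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(tree$genomes)) {
    g <- data.frame(genome_id = tree$genomes$genome_id,
                    taxid = tree$nodes$taxid[tree$genomes$taxon],
                    length = tree$genomes$length)
    write.table(g, paste0(path, ".genomes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  nodes <- read.delim(path, stringsAsFactors = FALSE)
  tree <- taxonomy(nodes)
  gpath <- paste0(path, ".genomes.tsv")
  if (file.exists(gpath)) {
    g <- read.delim(gpath, stringsAsFactors = FALSE)
    gt <- setNames(match(g$taxid, tree$nodes$taxid), g$genome_id)
    tree <- set_genomes(tree, gt, setNames(g$length, g$genome_id))
  }
  tree
}
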