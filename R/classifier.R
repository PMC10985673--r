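#' @title Read-level classification by distance-weighted voting
#' @name classifier
#' @description Each matched k-mer votes `(1 - hd/k)^k` for its label's
#'   taxon; votes are aggregated bottom-up over the taxonomy so a vote for
#'   a child also counts toward every ancestor. With
#'   `tau = max(total)/2` (realized at the root), at most one taxon per
#'   rank can exceed tau, and the read is assigned at the lowest rank where
#'   one does — unless that winner's total vote falls below the spurious-
#'   match filter `min_total_vote`.
NULL

#' Vote mass of a k-mer match
#'
#' `v(hd) = (1 - hd/k)^k`, dropping near-exponentially with distance: an
#' exact match casts a full vote of 1; two matches at hd = 5 (k = 32) sum
#' to less than 0.01, two at hd = 4 to less than 0.03 — the calibration
#' behind the default total-vote filter.
#'
#' @param hd Hamming distance in bases (vectorized, `0 <= hd <= k`).
#' @param k k-mer length.
#' @return vote masses in `[0, 1]`.
#' @export
vote_value <- function(hd, k = 32) {
  stopifnot(all(hd >= 0), all(hd <= k))
  (1 - hd / k)^k
}

#' Build a per-read vote table from k-mer matches
#'
#' Matches at distance `> d_max` (already excluded by lookup) or with an
#' unassigned label (taxon 0) cast no vote. Totals satisfy
#' `total(t) = direct(t) + sum(total(children))` and conserve mass:
#' `total(root) == sum(direct)`.
#'
#' @param matches data.frame with columns `distance` and `taxon` (internal
#'   ids; NA/0 rows are dropped) as returned by [lsh_lookup()].
#' @param tree a [taxonomy].
#' @param k k-mer length used for the vote weight.
#' @return an object of class `vote_table`: list with numeric vectors
#'   `direct` and `total` indexed by internal taxon id, plus `root_total`.
#' @export
collect_votes <- function(matches, tree, k = 32) {
  n <- n_taxa(tree)
  direct <- numeric(n)
  keep <- !is.na(matches$taxon) & matches$taxon > 0
  if (any(keep)) {
    v <- vote_value(matches$distance[keep], k)
    agg <- rowsum(v, matches$taxon[keep])
    direct[as.integer(rownames(agg))] <- agg[, 1]
  }
  total <- aggregate_votes(direct, tree)
  structure(list(direct = direct, total = total,
                 root_total = total[tree$root]),
            class = "vote_table")
}

# bottom-up sum over the taxonomy: children before parents
aggregate_votes <- function(direct, tree) {
  total <- direct
  parent <- tree$nodes$parent
  for (i in tree$agg_order) {
    p <- parent[i]
    if (p != 0) total[p] <- total[p] + total[i]
  }
  total
}

#' @export
print.vote_table <- function(x, ...) {
  cat(sprintf("<vote_table> root total %.4f over %d taxa with direct votes\n",
              x$root_total, sum(x$direct > 0)))
  invisible(x)
}

#' Classify one read from its vote table
#'
#' `tau` is half the maximum total vote (the root's, by monotonicity).
#' Ranks are scanned from species upward and the first taxon with
#' `total > tau` (strict, so an exact half-split pushes assignment one
#' rank up) is chosen; if its total vote is below `min_total_vote`, or no
#' votes were cast, the read is unclassified.
#'
#' @param votes a [collect_votes()] table.
#' @param tree a [taxonomy].
#' @param min_total_vote spurious-match filter on the winner's total vote
#'   (default 0.03, i.e. less than two hd-4 matches at k = 32).
#' @return one-row data.frame: `status` ("C"/"U"), `taxon` (internal id or
#'   NA), `rank`, `total_vote`, `root_vote`.
#' @export
classify_read <- function(votes, tree, min_total_vote = 0.03) {
  root_vote <- votes$root_total
  unclassified <- data.frame(status = "U", taxon = NA_integer_,
                             rank = NA_character_, total_vote = NA_real_,
                             root_vote = root_vote,
                             stringsAsFactors = FALSE)
  if (root_vote <= 0) return(unclassified)
  tau <- root_vote / 2
  for (r in tree$ranks) {
    cand <- taxa_at_rank(tree, r)
    cand <- cand[votes$total[cand] > tau]
    if (length(cand)) {
      t_hat <- cand[which.max(votes$total[cand])]  # unique by the tau rule
      if (votes$total[t_hat] < min_total_vote) return(unclassified)
      return(data.frame(status = "C", taxon = t_hat, rank = r,
                        total_vote = votes$total[t_hat],
                        root_vote = root_vote, stringsAsFactors = FALSE))
    }
  }
  unclassified
}

#' Classify a set of reads against a library
#'
#' Streams canonical k-mers of every read through [lsh_lookup()], lets
#' each matched k-mer with a labeled best match vote, and applies
#' [classify_read()] per read. Ties between equally distant labels were
#' already broken deterministically (smallest K index) by lookup.
#'
#' @param index a labeled [lsh_index()].
#' @param tree a [taxonomy].
#' @param reads named character vector of read sequences.
#' @param min_total_vote see [classify_read()].
#' @param d_max vote gate on match distance (defaults to the index's).
#' @param minimizer_window optional; must match the library build.
#' @param keep_votes also return the per-read vote tables (needed for
#'   profiling).
#' @param keep_matches also return the per-k-mer match records.
#' @return list with `assignments` (data.frame: read_id, status, taxon,
#'   rank, total_vote, root_vote, n_matched_kmers), and optionally
#'   `votes` (list of vote tables) and `matches`.
#' @export
classify_reads <- function(index, tree, reads,
                           min_total_vote = 0.03,
                           d_max = index$params$d_max,
                           minimizer_window = NULL,
                           keep_votes = FALSE, keep_matches = FALSE) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  stream <- reads_to_kmer_stream(reads, k = index$params$k,
                                 minimizer_window = minimizer_window)
  hits <- lsh_lookup(index, stream$kmers, d_max = d_max)
  hits$read <- stream$read
  n_reads <- length(reads)
  k <- index$params$k
  matched <- hits[!is.na(hits$distance), , drop = FALSE]
  by_read <- split(matched[c("distance", "taxon", "ref_index")],
                   factor(matched$read, levels = seq_len(n_reads)))
  votes_list <- vector("list", n_reads)
  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    votes <- collect_votes(by_read[[i]], tree, k)
    cls <- classify_read(votes, tree, min_total_vote)
    cls$read_id <- names(reads)[i]
    cls$n_matched_kmers <- nrow(by_read[[i]])
    rows[[i]] <- cls
    if (keep_votes) votes_list[[i]] <- votes
  }
  assignments <- do.call(rbind, rows)
  assignments <- assignments[, c("read_id", "status", "taxon", "rank",
                                 "total_vote", "root_vote",
                                 "n_matched_kmers")]
  rownames(assignments) <- NULL
  out <- list(assignments = assignments)
  if (keep_votes) { out$votes <- votes_list; names(out$votes) <- names(reads) }
  if (keep_matches) out$matches <- hits
  out
}
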