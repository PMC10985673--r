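#' @title Per-rank evaluation of classifications and profiles
#' @name metrics
#' @description Reads are scored rank by rank. A read is a *positive* at
#'   rank r when the reference library contains at least one genome of its
#'   true taxon at r (TP correct label, FP wrong label, FN no label at r),
#'   and a *negative* otherwise (TN no label, FP any label, which is
#'   necessarily wrong). Reads whose true lineage lacks rank r are skipped.
#'   An assignment at a rank above r provides no label at r and counts FN
#'   for positives — correct-but-less-specific is treated as a miss at r.
NULL

#' Score read assignments at one rank
#'
#' @param assignments data.frame from [classify_reads()] (`read_id`,
#'   `status`, `taxon`).
#' @param truth named integer vector: read_id -> true species-level
#'   internal taxon id.
#' @param tree a [taxonomy] with reference genomes attached (defines which
#'   taxa are represented).
#' @param rank one of [CANONICAL_RANKS].
#' @return an object of class `rank_contingency`: list with `rank`, `TP`,
#'   `FP`, `FN`, `TN` and `n_evaluated`.
#' @export
score_reads <- function(assignments, truth, tree, rank) {
  stopifnot(all(assignments$read_id %in% names(truth)))
  ref <- reference_taxa(tree, rank)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(assignments))) {
    true_sp <- truth[[assignments$read_id[i]]]
    true_r <- rank_of_lineage(tree, true_sp, rank)
    if (is.na(true_r)) next  # missing true rank: read skipped
    pred_r <- NA_integer_
    if (assignments$status[i] == "C")
      pred_r <- rank_of_lineage(tree, assignments$taxon[i], rank)
    if (true_r %in% ref) {  # positive
      if (is.na(pred_r)) fn <- fn + 1L
      else if (pred_r == true_r) tp <- tp + 1L
      else fp <- fp + 1L
    } else {                # negative
      if (is.na(pred_r)) tn <- tn + 1L
      else fp <- fp + 1L
    }
  }
  structure(list(rank = rank, TP = tp, FP = fp, FN = fn, TN = tn,
                 n_evaluated = tp + fp + fn + tn),
            class = "rank_contingency")
}

#' @export
print.rank_contingency <- function(x, ...) {
  cat(sprintf("<rank_contingency> %s: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$rank, x$TP, x$FP, x$FN, x$TN, x$n_evaluated))
  invisible(x)
}

#' Precision, recall and F1 from a contingency
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`; 0/0 scores 0.
#'
#' @param c a [score_reads()] contingency (or any list with TP/FP/FN).
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(c) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  c(precision = safe(c$TP, c$TP + c$FP),
    recall = safe(c$TP, c$TP + c$FN),
    f1 = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN))
}

# align two profiles on the union of taxa; unclassified mass is kept as a
# taxon of its own only when both profiles carry it, otherwise dropped and
# the remaining mass renormalized
align_profiles <- function(p, q, keep_unclassified = NULL) {
  get_vec <- function(x) {
    if (inherits(x, "rank_profile")) {
      v <- x$abundances[x$abundances > 0]
      if (x$unclassified > 0) v <- c(v, ".unclassified" = x$unclassified)
      v
    } else {
      x[x > 0]
    }
  }
  vp <- get_vec(p)
  vq <- get_vec(q)
  if (is.null(keep_unclassified))
    keep_unclassified <- ".unclassified" %in% names(vp) &&
                         ".unclassified" %in% names(vq)
  if (!keep_unclassified) {
    vp <- vp[names(vp) != ".unclassified"]
    vq <- vq[names(vq) != ".unclassified"]
    if (sum(vp) > 0) vp <- vp / sum(vp)
    if (sum(vq) > 0) vq <- vq / sum(vq)
  }
  taxa <- union(names(vp), names(vq))
  rbind(p = ifelse(taxa %in% names(vp), vp[taxa], 0),
        q = ifelse(taxa %in% names(vq), vq[taxa], 0))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum(|p - q|) / sum(p + q)` over the union of taxa (zero-filled);
#' 0 for identical profiles, 1 for disjoint supports.
#'
#' @param p,q `rank_profile` objects at the same rank, or named abundance
#'   vectors.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  m <- align_profiles(p, q)
  sum(abs(m[1, ] - m[2, ])) / sum(m)
}

#' L1 error between two profiles
#'
#' `sum(|p - q|)` over the union of taxa; in `[0, 2]` for normalized
#' profiles (`= 2 * bray_curtis` there).
#'
#' @inheritParams bray_curtis
#' @return L1 distance.
#' @export
l1_error <- function(p, q) {
  m <- align_profiles(p, q)
  sum(abs(m[1, ] - m[2, ]))
}

#' Shannon's equitability of a profile
#'
#' Shannon entropy over taxa with positive mass, normalized by the log of
#' their count: 1 for a perfectly even profile, 0 for a single taxon.
#'
#' @param p a `rank_profile` or named abundance vector (must have at least
#'   one positive entry; unclassified mass is excluded and the rest
#'   renormalized).
#' @return equitability in `[0, 1]`.
#' @export
shannon_equitability <- function(p) {
  v <- if (inherits(p, "rank_profile")) p$abundances else p
  v <- v[v > 0]
  stopifnot(length(v) >= 1)
  v <- v / sum(v)
  if (length(v) == 1) return(0)
  -sum(v * log(v)) / log(length(v))
}
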