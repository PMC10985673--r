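#' @title Per-rank abundance profiling from vote tables
#' @name profiler
#' @description Profiles are computed per rank, independently. By default
#'   each read's total votes at the rank are normalized to sum to one
#'   (equalizing read contributions) before summing over reads and
#'   renormalizing; the optional raw mode sums unnormalized totals. In
#'   unclassified mode the per-read denominator is the root total instead
#'   of the rank total, and the residual mass — votes parked at taxa above
#'   the rank, evidence for *some* descendant — flows to an artificial
#'   "unclassified" taxon, so profiles still sum to one.
NULL

#' Normalize one read's votes at a rank
#'
#' @param votes a [collect_votes()] table.
#' @param tree a [taxonomy].
#' @param rank one of [CANONICAL_RANKS].
#' @param include_unclassified if `TRUE`, divide by the root total and
#'   carry the residual as unclassified mass; otherwise divide by the sum
#'   of rank totals.
#' @return named numeric vector of normalized votes over the rank's taxa
#'   plus an `"unclassified"` element, or `NULL` when the read has no
#'   votes in the denominator (it then contributes nothing to profiles).
#' @export
normalize_read <- function(votes, tree, rank, include_unclassified = TRUE) {
  taxa <- taxa_at_rank(tree, rank)
  vr <- votes$total[taxa]
  denom <- if (include_unclassified) votes$root_total else sum(vr)
  if (denom <= 0) return(NULL)
  out <- setNames(vr / denom, taxa)
  c(out, unclassified = max(0, 1 - sum(out)))
}

#' Profile a sample from per-read vote tables
#'
#' @param votes_list list of [collect_votes()] tables (one per read), e.g.
#'   from `classify_reads(..., keep_votes = TRUE)$votes`.
#' @param tree a [taxonomy].
#' @param ranks ranks to profile (default all canonical ranks).
#' @param read_normalize default `TRUE`: normalize per read before
#'   summing; `FALSE` is the raw mode that sums totals directly, which
#'   weights reads by their match strength.
#' @param include_unclassified include the artificial unclassified taxon
#'   (default `TRUE`).
#' @return named list of `rank_profile` objects, one per rank; each has
#'   `abundances` (named by internal taxon id), `unclassified`, `rank`,
#'   and mode flags. Abundances plus unclassified sum to 1.
#' @export
profile_sample <- function(votes_list, tree, ranks = CANONICAL_RANKS,
                           read_normalize = TRUE,
                           include_unclassified = TRUE) {
  stopifnot(length(votes_list) >= 1)
  out <- list()
  for (r in ranks) {
    taxa <- taxa_at_rank(tree, r)
    acc <- setNames(numeric(length(taxa)), taxa)
    acc_un <- 0
    for (votes in votes_list) {
      if (read_normalize) {
        v <- normalize_read(votes, tree, r, include_unclassified)
        if (is.null(v)) next
        acc <- acc + v[as.character(taxa)]
        acc_un <- acc_un + v[["unclassified"]]
      } else {
        vr <- votes$total[taxa]
        acc <- acc + vr
        if (include_unclassified)
          acc_un <- acc_un + max(0, votes$root_total - sum(vr))
      }
    }
    tot <- sum(acc) + acc_un
    if (tot <= 0) {
      abund <- acc
      un <- 0
    } else {
      abund <- acc / tot
      un <- acc_un / tot
    }
    out[[r]] <- structure(
      list(rank = r, abundances = abund,
           unclassified = if (include_unclassified) un else 0,
           read_normalized = read_normalize,
           size_corrected = FALSE,
           unclassified_included = include_unclassified),
      class = "rank_profile")
  }
  out
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf(
    "<rank_profile> %s: %d taxa with mass, unclassified %.3f%s%s\n",
    x$rank, sum(x$abundances > 0), x$unclassified,
    if (x$read_normalized) "" else " (raw mode)",
    if (x$size_corrected) " (cell fractions)" else ""))
  invisible(x)
}

#' Genome-size correction of a profile
#'
#' Converts read fractions to cell fractions: abundances are rescaled
#' proportionally to `p_t / l_t` (mean reference genome length of the
#' taxon's clade) and renormalized. With uniform lengths this is the
#' identity. Unclassified mass has no genome length and is left untouched;
#' the classified taxa are renormalized within their original share.
#'
#' @param profile a `rank_profile`.
#' @param tree a [taxonomy] with genome lengths attached.
#' @return a corrected `rank_profile`.
#' @export
size_correct <- function(profile, tree) {
  lt <- taxon_genome_lengths(tree)
  taxa <- as.integer(names(profile$abundances))
  active <- profile$abundances > 0
  if (any(active & is.na(lt[taxa])))
    stop("no genome length for taxa: ",
         paste(taxa[active & is.na(lt[taxa])], collapse = ", "))
  w <- profile$abundances / lt[taxa]
  w[!active] <- 0
  tot <- sum(w)
  classified_share <- sum(profile$abundances)
  if (tot > 0) profile$abundances <- w / tot * classified_share
  profile$size_corrected <- TRUE
  profile
}

#' Write profiles in CAMI (Bioboxes) profiling format
#'
#' Emits the `@SampleID`/`@Version`/`@Ranks` header and one row per taxon
#' with TAXID, RANK, TAXPATH, TAXPATHSN and PERCENTAGE (0-100). Ranks are
#' written from superkingdom down; the artificial unclassified taxon gets
#' taxid `"unclassified"`.
#'
#' @param profiles list of `rank_profile` objects from [profile_sample()].
#' @param tree the [taxonomy].
#' @param path output file.
#' @param sample_id sample identifier for the header.
#' @return `path`, invisibly.
#' @export
write_cami_profile <- function(profiles, tree, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  ranks_out <- rev(intersect(CANONICAL_RANKS, names(profiles)))
  writeLines(c(paste0("@SampleID:", sample_id),
               "@Version:0.9.1",
               paste0("@Ranks:", paste(ranks_out, collapse = "|")),
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE"), con)
  for (r in ranks_out) {
    pr <- profiles[[r]]
    taxa <- as.integer(names(pr$abundances))
    for (i in seq_along(taxa)) {
      if (pr$abundances[i] <= 0) next
      lin <- lineage_ids(tree, taxa[i])
      writeLines(paste(tree$nodes$taxid[taxa[i]], r,
                       paste(tree$nodes$taxid[lin], collapse = "|"),
                       paste(tree$nodes$name[lin], collapse = "|"),
                       format(100 * pr$abundances[i], scientific = FALSE),
                       sep = "\t"), con)
    }
    if (pr$unclassified > 0)
      writeLines(paste("unclassified", r, "unclassified", "unclassified",
                       format(100 * pr$unclassified, scientific = FALSE),
                       sep = "\t"), con)
  }
  invisible(path)
}

# canonical-rank ancestors of t, highest first, ending at t's rank
lineage_ids <- function(tree, t) {
  out <- integer(0)
  a <- t
  while (a != 0) {
    if (!is.na(tree$rank_index[a])) out <- c(a, out)
    a <- tree$nodes$parent[a]
  }
  out
}

#' Flatten profiles to a plain TSV-ready data.frame
#'
#' @param profiles list of `rank_profile` objects.
#' @param tree the [taxonomy].
#' @return data.frame with rank, taxid, name, abundance rows (including
#'   unclassified).
#' @export
profiles_to_df <- function(profiles, tree) {
  rows <- list()
  for (r in names(profiles)) {
    pr <- profiles[[r]]
    taxa <- as.integer(names(pr$abundances))
    keep <- pr$abundances > 0
    rows[[r]] <- rbind(
      data.frame(rank = r, taxid = tree$nodes$taxid[taxa[keep]],
                 name = tree$nodes$name[taxa[keep]],
                 abundance = unname(pr$abundances[keep]),
                 stringsAsFactors = FALSE),
      if (pr$unclassified > 0)
        data.frame(rank = r, taxid = NA_integer_, name = "unclassified",
                   abundance = pr$unclassified, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
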