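#' @title Bit-sampling LSH index over reference k-mers
#' @name lsh_index
#' @description For each of `l` tables, `h` fixed base positions of the
#'   packed k-mer are extracted to form a row index into a `2^(2h) x b`
#'   bucket matrix of pointers into the append-only encoding array K.
#'   Lookups follow at most `b*l` pointers, compute true Hamming distances,
#'   and therefore never return a false positive; misses follow the
#'   analytic collision law `rho(d)`.
NULL

round_half_up <- function(x) floor(x + 0.5)

#' LSH parameter set
#'
#' @param k k-mer length in bases (default 32, the production setting).
#' @param h sampled base positions per table (default 15; desk-scale test
#'   worlds use smaller h so tables fit in memory).
#' @param l number of hash tables (default 2).
#' @param b bucket width in slots (default 7).
#' @param p target Hamming-distance radius the tables are tuned to
#'   guarantee (default 3).
#' @param d_max maximum Hamming distance at which a match may vote;
#'   defaults to `round_half_up(3p/2)` = 5 at `p = 3`.
#' @return an object of class `lsh_params`.
#' @export
lsh_params <- function(k = 32, h = 15, l = 2, b = 7, p = 3,
                       d_max = round_half_up(3 * p / 2)) {
  stopifnot(k >= 1, k <= 32, h >= 1, h < k, l >= 1, b >= 1,
            p >= 0, d_max >= p, d_max <= k)
  structure(list(k = as.integer(k), h = as.integer(h), l = as.integer(l),
                 b = as.integer(b), p = as.integer(p),
                 d_max = as.integer(d_max)),
            class = "lsh_params")
}

#' @export
print.lsh_params <- function(x, ...) {
  cat(sprintf("<lsh_params> k=%d h=%d l=%d b=%d p=%d d_max=%d\n",
              x$k, x$h, x$l, x$b, x$p, x$d_max))
  invisible(x)
}

#' Collision probability of two k-mers at Hamming distance d
#'
#' Probability that two independent k-mers at distance `d` share at least
#' one table hash: `rho(d) = 1 - (1 - (1 - d/k)^h)^l`. `d` may be
#' fractional, so a normalized distance can be evaluated on the analytic
#' curve directly.
#'
#' @param d Hamming distance in bases (vectorized, `0 <= d <= k`).
#' @param params an [lsh_params()] object.
#' @return collision probabilities in `[0, 1]`.
#' @export
rho <- function(d, params = lsh_params()) {
  stopifnot(all(d >= 0), all(d <= params$k))
  1 - (1 - (1 - d / params$k)^params$h)^params$l
}

#' Expected number of matching k-mers on a read
#'
#' A read of length `L` offers `L - k + 1` k-mers, each colliding with a
#' reference at normalized distance `d_norm` with probability
#' `rho(d_norm * k)`, so the expectation is `(L - k + 1) * rho(d_norm * k)`.
#' At the defaults (k=32, h=15, l=2) a 150 bp read at 25% distance yields
#' 3.2 expected matches (1.6 with a single table).
#'
#' @param L read length in bases, `L >= k`.
#' @param d_norm normalized distance in `[0, 1]` of the read to its closest
#'   reference.
#' @param params an [lsh_params()] object.
#' @return expected match count.
#' @export
expected_matches <- function(L, d_norm, params = lsh_params()) {
  stopifnot(L >= params$k, d_norm >= 0, d_norm <= 1)
  (L - params$k + 1) * rho(d_norm * params$k, params)
}

#' Create an empty LSH index
#'
#' The `h` base positions of each table are drawn without replacement from
#' `0:(k-1)` under `seed` (and sorted), so the hash spec is regenerable
#' bit-identically from the seed alone.
#'
#' @param params an [lsh_params()] object. Tables are dense: memory is
#'   `2^(2h) * b * l` 4-byte slots, so keep `h <= 12` on desktop hardware.
#' @param seed integer RNG seed for position sampling.
#' @param positions optional explicit hash spec: an `l x h` matrix of
#'   0-based base positions, distinct within each row (overrides the
#'   seeded sampling; useful for controlled experiments).
#' @return an object of class `lsh_index` (mutable; inserts modify it in
#'   place).
#' @export
lsh_index <- function(params = lsh_params(), seed = 1, positions = NULL) {
  if (params$h > 13)
    warning("h = ", params$h, " allocates 2^", 2 * params$h,
            " rows per table; this may exhaust memory")
  if (is.null(positions)) {
    positions <- withr_seed(seed, {
      t(vapply(seq_len(params$l),
               function(i) sort(sample.int(params$k, params$h) - 1L),
               integer(params$h)))
    })
  } else {
    positions <- matrix(as.integer(positions), nrow = params$l)
    stopifnot(ncol(positions) == params$h,
              all(positions >= 0), all(positions < params$k),
              all(apply(positions, 1, anyDuplicated) == 0))
  }
  ptr <- cpp_index_new(params$k, params$h, params$l, params$b,
                       params$p, params$d_max, positions)
  structure(list(ptr = ptr, params = params, seed = as.integer(seed),
                 positions = positions),
            class = "lsh_index")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.lsh_index <- function(x, ...) {
  cat(sprintf("<lsh_index> %d k-mer(s), k=%d h=%d l=%d b=%d (seed %d)\n",
              index_size(x), x$params$k, x$params$h, x$params$l,
              x$params$b, x$seed))
  invisible(x)
}

#' Number of stored reference k-mers
#' @param index an [lsh_index()].
#' @return integer `|K|`.
#' @export
index_size <- function(index) cpp_index_size(index$ptr)

#' Hash row of k-mers for one table
#'
#' @param index an [lsh_index()].
#' @param kmers an `encoded_kmers` vector.
#' @param table table number in `1:l`.
#' @return numeric vector of row indices in `[0, 2^(2h))`.
#' @export
table_hash <- function(index, kmers, table = 1) {
  stopifnot(table >= 1, table <= index$params$l)
  cpp_table_hash(kmers$hi, kmers$lo, index$positions[table, ])
}

#' Insert k-mers into the index
#'
#' Already-present k-mers are not duplicated (`|K|` grows only for new
#' words). New k-mers are appended to K and a pointer is placed in each
#' table's hash row; a full row keeps each of its m insertion attempts with
#' probability `b/m` by reservoir-style random replacement, making k-mer
#' retention unbiased by insertion order. Uses R's RNG: seed the session
#' (or use [build_library()], which seeds for you) for reproducibility.
#'
#' @param index an [lsh_index()] (modified in place).
#' @param kmers an `encoded_kmers` vector.
#' @return invisibly, a logical vector: was each k-mer newly stored?
#' @export
lsh_insert <- function(index, kmers) {
  stopifnot(inherits(kmers, "encoded_kmers"), kmers$k == index$params$k)
  invisible(cpp_index_insert(index$ptr, kmers$hi, kmers$lo))
}

#' Closest-match lookup
#'
#' Follows the at most `b*l` pointers in the query's hash rows,
#' deduplicates candidates, computes true Hamming distances, and reports
#' the minimum-distance candidate (ties broken toward the smallest K
#' index) when its distance is `<= d_max`; otherwise a no-match (NA row).
#' Reported distances are exact, so there are no false positives.
#'
#' @param index an [lsh_index()].
#' @param kmers an `encoded_kmers` vector of queries.
#' @param d_max maximum reportable distance (defaults to the index's).
#' @return data.frame with one row per query: `ref_index`, `distance`,
#'   `taxon` (internal taxon id, 0 if the entry was never labeled; NA if no
#'   match).
#' @export
lsh_lookup <- function(index, kmers, d_max = index$params$d_max) {
  stopifnot(inherits(kmers, "encoded_kmers"), kmers$k == index$params$k)
  out <- cpp_index_lookup(index$ptr, kmers$hi, kmers$lo, as.integer(d_max))
  data.frame(ref_index = out$ref_index, distance = out$distance,
             taxon = out$taxon)
}

#' Retrieve stored k-mers by K index
#' @param index an [lsh_index()].
#' @param at integer vector of 1-based K indices.
#' @return an `encoded_kmers` vector.
#' @export
index_kmers <- function(index, at) {
  out <- cpp_index_kmers(index$ptr, as.integer(at))
  new_encoded_kmers(out$hi, out$lo, index$params$k)
}

#' Per-entry taxon labels and genome counts
#' @param index an [lsh_index()].
#' @return `index_labels`: integer vector of internal taxon ids (0 =
#'   unassigned); `index_counts`: integer vector of genome-occurrence
#'   counts Ni, both parallel to K.
#' @export
index_labels <- function(index) cpp_index_labels(index$ptr)

#' @rdname index_labels
#' @export
index_counts <- function(index) cpp_index_counts(index$ptr)

#' Suggest LSH parameters for a library size
#'
#' Simplified sizing rule: with `b = 7` and `l = 2` fixed, choose the
#' smallest `h >= 8` whose total slot capacity `2^(2h) * b` is at least
#' `num_kmers * l`; if the implied memory (4 bytes/slot across tables plus
#' 8 bytes per K entry and 2 per label) exceeds `memory_budget`, `h` is
#' lowered until it fits (capacity then falls short, which the tables
#' absorb by reservoir eviction). Errors when even `h = 8` does not fit.
#'
#' @param num_kmers expected number of distinct reference k-mers.
#' @param memory_budget bytes available (default unlimited).
#' @param b,l bucket width and table count used by the rule.
#' @return an [lsh_params()] object.
#' @export
suggest_params <- function(num_kmers, memory_budget = Inf, b = 7, l = 2) {
  stopifnot(num_kmers >= 1)
  bytes_at <- function(h) 4^h * b * l * 4 + num_kmers * 8 + num_kmers * 2
  h <- 8
  while (4^h * b < num_kmers * l && h < 15) h <- h + 1
  while (bytes_at(h) > memory_budget && h > 8) h <- h - 1
  if (bytes_at(h) > memory_budget)
    stop("memory budget of ", memory_budget,
         " bytes cannot fit any index with h >= 8 (needs ",
         format(bytes_at(8), big.mark = ","), " bytes)")
  lsh_params(h = h, b = b, l = l)
}

#' Save / load a reference library directory
#'
#' The directory holds `metadata.json` (parameters, seed, hash positions,
#' versions), flat binary arrays for K, labels, counts and the hash tables,
#' and optionally the taxonomy as a TSV. Loading reproduces lookups
#' bit-identically.
#'
#' @param index an [lsh_index()].
#' @param dir library directory (created if needed).
#' @param tree optional [taxonomy] to store alongside.
#' @return `save_library`: the directory, invisibly. `load_library`: a list
#'   with elements `index` and (if saved) `tree`.
#' @export
save_library <- function(index, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- cpp_index_export(index$ptr)
  meta <- list(
    format = "lshtax-library-1",
    params = unclass(index$params),
    seed = index$seed,
    positions = index$positions,
    n_kmers = length(st$K_hi),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lshtax"))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  write_bin <- function(x, name, what) {
    con <- file(file.path(dir, name), "wb")
    on.exit(close(con))
    writeBin(if (what == "double") as.numeric(x) else as.integer(x), con,
             size = if (what == "double") 8L else 4L)
  }
  write_bin(st$K_hi, "K_hi.bin", "double")
  write_bin(st$K_lo, "K_lo.bin", "double")
  write_bin(st$labels, "labels.bin", "int")
  write_bin(st$counts, "counts.bin", "int")
  for (t in seq_len(index$params$l)) {
    write_bin(st$tables[[t]], sprintf("table%d.bin", t), "int")
    write_bin(st$attempts[[t]], sprintf("attempts%d.bin", t), "int")
  }
  if (!is.null(tree)) write_taxonomy(tree, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "lshtax-library-1"))
    stop("not an lshtax library: ", dir)
  pr <- meta$params
  params <- lsh_params(k = pr$k, h = pr$h, l = pr$l, b = pr$b, p = pr$p,
                       d_max = pr$d_max)
  read_bin <- function(name, what, n) {
    con <- file(file.path(dir, name), "rb")
    on.exit(close(con))
    readBin(con, what, n = n, size = if (what == "double") 8L else 4L)
  }
  n <- meta$n_kmers
  nrow_slots <- 4^params$h * params$b
  positions <- matrix(as.integer(meta$positions), nrow = params$l)
  st <- list(k = params$k, h = params$h, l = params$l, b = params$b,
             p = params$p, dmax = params$d_max, positions = positions,
             K_hi = read_bin("K_hi.bin", "double", n),
             K_lo = read_bin("K_lo.bin", "double", n),
             labels = read_bin("labels.bin", "integer", n),
             counts = read_bin("counts.bin", "integer", n),
             tables = lapply(seq_len(params$l), function(t)
               read_bin(sprintf("table%d.bin", t), "integer", nrow_slots)),
             attempts = lapply(seq_len(params$l), function(t)
               read_bin(sprintf("attempts%d.bin", t), "integer",
                        4^params$h)))
  ptr <- cpp_index_import(st)
  index <- structure(list(ptr = ptr, params = params,
                          seed = as.integer(meta$seed),
                          positions = positions),
                     class = "lsh_index")
  tree <- NULL
  tax_path <- file.path(dir, "taxonomy.tsv")
  if (file.exists(tax_path)) tree <- read_taxonomy(tax_path)
  list(index = index, tree = tree)
}
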