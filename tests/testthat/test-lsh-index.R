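test_that("lsh_params validates and derives d_max = round-half-up(3p/2)", {
  p <- lsh_params()
  expect_equal(c(p$k, p$h, p$l, p$b, p$p, p$d_max), c(32, 15, 2, 7, 3, 5))
  expect_equal(lsh_params(p = 2)$d_max, 3)  # round_half_up(3) = 3
  expect_equal(lsh_params(p = 1)$d_max, 2)  # 1.5 rounds up, not to even
  expect_error(lsh_params(h = 32), "h < k")
})

test_that("rho follows the collision law and reproduces the printed curve", {
  prm <- lsh_params()
  expect_equal(rho(0, prm), 1.0)
  expect_equal(rho(32, prm), 0.0)
  expect_equal(round(expected_matches(150, 0.25, prm), 1), 3.2)
  expect_equal(round(expected_matches(150, 0.25, lsh_params(l = 1)), 1), 1.6)
  expect_equal(expected_matches(32, 0, prm), 1.0)
  # manual formula spot-check at fractional d
  d <- 6.72
  expect_equal(rho(d, prm), 1 - (1 - (1 - d / 32)^15)^2)
})

test_that("table_hash extracts sampled positions (string oracle)", {
  idx <- lsh_index(lsh_params(h = 8, b = 2), seed = 5)
  allA <- encode_kmer(strrep("A", 32))
  for (t in 1:2) expect_equal(table_hash(idx, allA, t), 0)

  set.seed(107)
  s <- random_kmer_strings(200)
  km <- encode_kmer(s)
  for (t in 1:2) {
    pos1 <- idx$positions[t, ] + 1  # 1-based string positions
    oracle <- vapply(s, function(x) {
      sub <- paste(strsplit(x, "")[[1]][pos1], collapse = "")
      e <- encode_kmer(sub, 8)
      e$hi * 2^32 + e$lo
    }, 0, USE.NAMES = FALSE)
    expect_equal(table_hash(idx, km, t), oracle)
  }
  # mutating a position outside the sampled set leaves the row unchanged
  out_pos <- setdiff(0:31, idx$positions[1, ])[1]
  s2 <- s[1]
  substr(s2, out_pos + 1, out_pos + 1) <-
    setdiff(BASES4, substr(s2, out_pos + 1, out_pos + 1))[1]
  expect_equal(table_hash(idx, encode_kmer(s2), 1),
               table_hash(idx, km[1], 1))
})

test_that("insert deduplicates and lookup finds exact matches", {
  idx <- lsh_index(lsh_params(h = 8, b = 4), seed = 9)
  set.seed(108)
  km <- encode_kmer(random_kmer_strings(50))
  lsh_insert(idx, km[1])
  hit <- lsh_lookup(idx, km[1])
  expect_equal(hit$distance, 0L)
  expect_equal(hit$ref_index, 1L)
  lsh_insert(idx, km[1])
  expect_equal(index_size(idx), 1)
  lsh_insert(idx, km)
  expect_equal(index_size(idx), 50)
  # a query sharing no row with stored k-mers yields no match:
  # distances reported are true, so an all-distant query returns NA
  far <- encode_kmer(strrep("C", 32))
  res <- lsh_lookup(idx, far)
  expect_true(is.na(res$distance))
})

test_that("lookup reports true distances and deterministic ties", {
  idx <- lsh_index(lsh_params(h = 6, b = 16), seed = 10)
  set.seed(109)
  s <- random_kmer_strings(200)
  lsh_insert(idx, encode_kmer(s))
  q <- random_kmer_strings(200)
  res <- lsh_lookup(idx, encode_kmer(q), d_max = 32)
  got <- !is.na(res$ref_index)
  expect_true(any(got))
  # no false positives: reported distance equals the string-oracle HD
  expect_equal(res$distance[got],
               str_hd(q[got], s[res$ref_index[got]]))
})

test_that("bucket overflow keeps each k-mer with reservoir probability", {
  # craft 30 k-mers identical at table 1's two sampled positions with
  # l = 1, b = 3: every insert targets the same row; the first k-mer
  # should survive with probability b/m = 3/30 = 0.1
  prm <- lsh_params(h = 2, l = 1, b = 3, p = 0, d_max = 0)
  probe <- lsh_index(prm, seed = 1)
  keep_pos <- probe$positions[1, ] + 1
  set.seed(110)
  base <- random_kmer_strings(1)
  mk <- function() {
    ch <- strsplit(base, "")[[1]]
    at <- setdiff(1:32, keep_pos)
    ch[at] <- sample(BASES4, length(at), TRUE)
    paste(ch, collapse = "")
  }
  survived <- 0L
  n_trials <- 1000
  m <- 30
  for (trial in seq_len(n_trials)) {
    kms <- unique(vapply(seq_len(m), function(i) mk(), ""))
    while (length(kms) < m) kms <- unique(c(kms, mk()))
    idx <- lsh_index(prm, seed = 1)
    set.seed(trial)
    lsh_insert(idx, encode_kmer(kms))
    hit <- lsh_lookup(idx, encode_kmer(kms[1]), d_max = 0)
    if (!is.na(hit$distance)) survived <- survived + 1L
  }
  p_expect <- prm$b / m  # 3/30
  se <- sqrt(p_expect * (1 - p_expect) / n_trials)
  expect_lt(abs(survived / n_trials - p_expect), 3 * se)
})

test_that("neighbor recall matches rho(d) within Monte-Carlo error", {
  # disjoint tables + i.i.d. per-site mutation make Eq. 1 exact; see the
  # acceptance suite for the full-scale version and the rationale
  prm <- lsh_params(h = 8, l = 2, b = 32, p = 3, d_max = 8)
  set.seed(111)
  pos16 <- sample.int(32, 16) - 1L
  idx <- lsh_index(prm, positions = rbind(sort(pos16[1:8]),
                                          sort(pos16[9:16])))
  stored <- unique(random_kmer_strings(2^11 + 20))[seq_len(2^11)]
  lsh_insert(idx, encode_kmer(stored))
  n_trials <- 500  # per distance; the acceptance suite runs 2000
  for (d in c(1, 3, 5, 8)) {
    at <- sample.int(2^11, n_trials, TRUE)
    qs <- vapply(stored[at], function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(32) < d / 32)
      for (i in hit) ch[i] <- sample(setdiff(BASES4, ch[i]), 1)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    found <- lsh_lookup(idx, encode_kmer(qs), d_max = 32)$ref_index
    hit_rate <- mean(!is.na(found) & found == at)
    p <- rho(d, prm)
    se <- sqrt(p * (1 - p) / n_trials)
    expect_lt(abs(hit_rate - p), 3 * se + 1e-9)
  }
})

test_that("suggest_params implements the sizing rule", {
  expect_equal(suggest_params(1)$h, 8)
  # num = 2^20, b = 7, l = 2: smallest h with 4^h * 7 >= 2^21 is 10
  expect_equal(suggest_params(2^20)$h, 10)
  expect_true(4^10 * 7 >= 2^21 && 4^9 * 7 < 2^21)
  expect_error(suggest_params(10, memory_budget = 1000), "memory budget")
  # a budget between h=8 and the capacity-satisfying h lowers h
  p <- suggest_params(2^20, memory_budget = 4^9 * 7 * 2 * 4 + 2^20 * 10)
  expect_equal(p$h, 9)
})

test_that("libraries round-trip through save/load bit-identically", {
  world <- small_world(seed = 21, genome_length = 3000)
  idx <- build_library(world$genomes, world$tree, small_params(h = 8),
                       seed = 33)
  dir <- file.path(tempdir(), "libtest-roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  save_library(idx, dir, tree = world$tree)
  lib <- load_library(dir)
  expect_equal(index_size(lib$index), index_size(idx))
  expect_identical(index_labels(lib$index), index_labels(idx))
  expect_identical(index_counts(lib$index), index_counts(idx))
  set.seed(112)
  q <- encode_kmer(random_kmer_strings(500))
  expect_identical(lsh_lookup(lib$index, q, d_max = 32),
                   lsh_lookup(idx, q, d_max = 32))
  expect_equal(nrow(lib$tree$nodes), nrow(world$tree$nodes))
  # same seed, same genome order: bit-identical rebuild
  idx2 <- build_library(world$genomes, world$tree, small_params(h = 8),
                        seed = 33)
  expect_identical(lshtax:::cpp_index_export(idx$ptr),
                   lshtax:::cpp_index_export(idx2$ptr))
})
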