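test_that("p_update matches its closed form and limits", {
  expect_equal(p_update(1), 1.0)            # 4/4 + 1/25 capped at 1
  expect_equal(p_update(5), 1.0)            # rare k-mers always labeled
  expect_equal(p_update(6), 0.84)           # 4/5 + 0.04
  expect_equal(p_update(21), 0.24)          # 4/20 + 0.04
  expect_equal(p_update(1e6), 1 / 25, tolerance = 1e-3)
  ni <- 1:200
  expect_true(all(diff(p_update(ni)) <= 0))
  expect_true(all(p_update(ni) > 0 & p_update(ni) <= 1))
})

test_that("genome occurrence counts Ni are per-distinct-genome", {
  tree <- fixture_tree()
  set.seed(201)
  seqA <- paste(sample(BASES4, 500, TRUE), collapse = "")
  prm <- lsh_params(h = 8, b = 16)

  # one genome, (near-certainly) unique k-mers: all Ni = 1
  gt <- setNames(fx_id(tree, "s1"), "gA")
  t1 <- set_genomes(tree, gt)
  idx <- build_library(c(gA = seqA), t1, prm, seed = 1)
  expect_true(all(index_counts(idx) == 1))

  # the same sequence as two genomes: all Ni = 2, |K| unchanged
  t2 <- set_genomes(tree, setNames(c(fx_id(tree, "s1"), fx_id(tree, "s2")),
                                   c("gA", "gB")))
  idx2 <- build_library(c(gA = seqA, gB = seqA), t2, prm, seed = 1)
  expect_equal(index_size(idx2), index_size(idx))
  expect_true(all(index_counts(idx2) == 2))

  # a planted 32-mer shared by 3 otherwise-random genomes has Ni = 3
  planted <- random_kmer_strings(1, 32)
  mkg <- function() paste0(random_kmer_strings(1, 100), planted,
                           random_kmer_strings(1, 100))
  t3 <- set_genomes(tree, setNames(c(fx_id(tree, "s1"), fx_id(tree, "s2"),
                                     fx_id(tree, "s4")),
                                   c("g1", "g2", "g3")))
  idx3 <- build_library(c(g1 = mkg(), g2 = mkg(), g3 = mkg()), t3, prm,
                        seed = 2)
  hit <- lsh_lookup(idx3, canonical_kmer(planted), d_max = 0)
  expect_equal(index_counts(idx3)[hit$ref_index], 3L)

  # a k-mer repeated within one genome still counts once
  idx4 <- build_library(c(gA = paste0(planted, planted)), t1, prm, seed = 3)
  hit4 <- lsh_lookup(idx4, canonical_kmer(planted), d_max = 0)
  expect_equal(index_counts(idx4)[hit4$ref_index], 1L)

  expect_error(build_library(c(gZ = seqA), t1, prm), "missing from")
})

test_that("forcing p_update to 1 reproduces the hard LCA exactly", {
  tree <- fixture_tree()
  set.seed(202)
  # four related genomes with heavy sharing: a core sequence plus noise
  core <- paste(sample(BASES4, 400, TRUE), collapse = "")
  gnm <- function() paste0(core, paste(sample(BASES4, 120, TRUE),
                                       collapse = ""))
  genomes <- c(gA = gnm(), gB = gnm(), gC = gnm(), gD = gnm())
  species <- setNames(fx_id(tree, c("s1", "s3", "s2", "s4")),
                      names(genomes))
  t4 <- set_genomes(tree, species)
  prm <- lsh_params(h = 8, b = 64)
  # s = 1e6 makes p_update(Ni) = 1 for all realistic Ni... no:
  # p_update = w/max(Ni+w-s, w) = w/w = 1 while Ni <= s
  idx <- build_library(genomes, t4, prm,
                       lca_params = soft_lca_params(s = 1e6), seed = 5)
  # oracle: hard LCA of the species of all genomes containing each k-mer
  kset <- lapply(genomes, function(g)
    decode_kmer(read_to_kmers(g, 32)))
  stored <- index_kmers(idx, seq_len(index_size(idx)))
  stored_s <- decode_kmer(stored)
  expected <- vapply(stored_s, function(km) {
    present <- vapply(kset, function(ks) km %in% ks, TRUE)
    lca_set(t4, unname(species[present]))
  }, 0L, USE.NAMES = FALSE)
  expect_identical(index_labels(idx), expected)
})

test_that("soft-LCA labels are invariant to genome processing order", {
  world <- small_world(seed = 23, genome_length = 4000)
  prm <- lsh_params(h = 9, b = 16)  # ample buckets: no eviction
  idx_f <- build_library(world$genomes, world$tree, prm, seed = 77)
  idx_r <- build_library(rev(world$genomes), world$tree, prm, seed = 77)
  # same k-mer set, same labels (coins depend on k-mer and genome only)
  kf <- decode_kmer(index_kmers(idx_f, seq_len(index_size(idx_f))))
  kr <- decode_kmer(index_kmers(idx_r, seq_len(index_size(idx_r))))
  of <- order(kf); or <- order(kr)
  expect_identical(kf[of], kr[or])
  expect_identical(index_labels(idx_f)[of], index_labels(idx_r)[or])
})

test_that("the 20-of-a-genus vs 1-outlier scenario matches the closed form", {
  # 21 genomes all consisting of one shared 32-mer: Ni = 21, pu = 0.24.
  # The label stays in the genus clade iff the outlier's coin fails and at
  # least one genus coin succeeds: p = (1-pu) * (1 - (1-pu)^20).
  lin <- data.frame(
    genome_id = sprintf("g%02d", 1:21),
    superkingdom = "sk",
    phylum = c(rep("pA", 20), "pB"),
    class = c(rep("cA", 20), "cB"),
    order = c(rep("oA", 20), "oB"),
    family = c(rep("fA", 20), "fB"),
    genus = c(rep("geA", 20), "geB"),
    species = c(sprintf("spA%02d", 1:20), "spB"),
    stringsAsFactors = FALSE)
  tree <- lineages_to_taxonomy(lin)
  genus_a <- taxon_by_name(tree, "geA")
  set.seed(203)
  shared <- random_kmer_strings(1, 32)
  genomes <- setNames(rep(shared, 21), lin$genome_id)
  prm <- lsh_params(h = 2, l = 1, b = 4, p = 0, d_max = 0)

  pu <- p_update(21)
  p_form <- (1 - pu) * (1 - (1 - pu)^20)
  n_rep <- 4000
  in_genus <- 0L
  for (r in seq_len(n_rep)) {
    idx <- build_library(genomes, tree, prm, seed = r)
    lab <- index_labels(idx)[1]
    if (lab > 0 && identical(rank_of_lineage(tree, lab, "genus"), genus_a))
      in_genus <- in_genus + 1L
  }
  se <- sqrt(p_form * (1 - p_form) / n_rep)
  expect_lt(abs(in_genus / n_rep - p_form), 3 * se)
})

test_that("build_report tallies labels and Ni", {
  world <- small_world(seed = 25, genome_length = 3000)
  idx <- build_library(world$genomes, world$tree, small_params(h = 8),
                       seed = 9)
  rep <- build_report(idx, world$tree)
  expect_equal(rep$n_kmers, index_size(idx))
  expect_equal(sum(rep$labels_by_rank), rep$n_kmers)
  expect_true("species" %in% names(rep$labels_by_rank))
})
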