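test_that("normalize_read divides by rank total or root total", {
  tree <- fixture_tree()
  # all mass under one genus
  vt <- make_vote_table(tree, c(s1 = 0.7, g1 = 0.3))
  v <- normalize_read(vt, tree, "genus", include_unclassified = FALSE)
  expect_equal(unname(v[as.character(fx_id(tree, "g1"))]), 1.0)

  # unclassified mode: votes cast at a phylum carry no species signal
  vt2 <- make_vote_table(tree, c(p1 = 1))
  v2 <- normalize_read(vt2, tree, "species", include_unclassified = TRUE)
  expect_equal(unname(v2[["unclassified"]]), 1.0)
  expect_true(all(v2[setdiff(names(v2), "unclassified")] == 0))

  # plain proportional normalization at a rank
  vt3 <- make_vote_table(tree, c(s1 = 0.2, s2 = 0.3, s3 = 0.5))
  v3 <- normalize_read(vt3, tree, "species", include_unclassified = FALSE)
  expect_equal(unname(v3[as.character(fx_id(tree, c("s1", "s2", "s3")))]),
               c(0.2, 0.3, 0.5))

  # a read with no votes contributes nothing
  expect_null(normalize_read(make_vote_table(tree, c(s1 = 0)), tree,
                             "species"))
})

test_that("profile_sample equalizes reads by default, raw mode does not", {
  tree <- fixture_tree()
  # two reads with root totals 1.0 and 0.1 voting different species
  votes <- list(make_vote_table(tree, c(s1 = 1.0)),
                make_vote_table(tree, c(s2 = 0.1)))
  pr <- profile_sample(votes, tree, ranks = "species")$species
  a <- pr$abundances
  expect_equal(unname(a[as.character(fx_id(tree, "s1"))]), 0.5)
  expect_equal(unname(a[as.character(fx_id(tree, "s2"))]), 0.5)
  raw <- profile_sample(votes, tree, ranks = "species",
                        read_normalize = FALSE)$species
  expect_equal(unname(raw$abundances[as.character(fx_id(tree, "s1"))]),
               10 / 11)
  expect_equal(unname(raw$abundances[as.character(fx_id(tree, "s2"))]),
               1 / 11)

  # identical reads from one species: full mass on its lineage at all ranks
  votes1 <- replicate(5, make_vote_table(tree, c(s1 = 0.8)),
                      simplify = FALSE)
  prof <- profile_sample(votes1, tree)
  for (r in CANONICAL_RANKS) {
    anc <- rank_of_lineage(tree, fx_id(tree, "s1"), r)
    expect_equal(unname(prof[[r]]$abundances[as.character(anc)]), 1.0)
  }
})

test_that("profiles sum to one and are scale-invariant per read", {
  tree <- fixture_tree()
  set.seed(401)
  rand_votes <- function(scale = 1) {
    nms <- sample(tree$nodes$name, 3)
    make_vote_table(tree, setNames(runif(3) * scale, nms))
  }
  votes <- replicate(20, rand_votes(), simplify = FALSE)
  for (un in c(TRUE, FALSE)) {
    prof <- profile_sample(votes, tree, include_unclassified = un)
    for (pr in prof)
      expect_equal(sum(pr$abundances) + pr$unclassified, 1.0,
                   tolerance = 1e-9)
  }
  # scaling one read's votes by a positive constant changes nothing
  votes_scaled <- votes
  votes_scaled[[3]] <- make_vote_table(
    tree, setNames(votes[[3]]$direct[votes[[3]]$direct > 0] * 50,
                   tree$nodes$name[which(votes[[3]]$direct > 0)]))
  p1 <- profile_sample(votes, tree)
  p2 <- profile_sample(votes_scaled, tree)
  for (r in CANONICAL_RANKS)
    expect_equal(p1[[r]]$abundances, p2[[r]]$abundances, tolerance = 1e-12)
})

test_that("size correction rescales by inverse genome length", {
  tree <- fixture_tree()
  gt <- setNames(fx_id(tree, c("s1", "s2")), c("gx", "gy"))

  # uniform lengths: identity
  t_eq <- set_genomes(tree, gt, c(gx = 1e6, gy = 1e6))
  votes <- list(make_vote_table(tree, c(s1 = 1)),
                make_vote_table(tree, c(s2 = 1)))
  pr <- profile_sample(votes, t_eq, ranks = "species")$species
  pc <- size_correct(pr, t_eq)
  expect_equal(pc$abundances, pr$abundances, tolerance = 1e-12)

  # p = (0.5, 0.5), l = (1 Mb, 2 Mb) -> (2/3, 1/3)
  t_neq <- set_genomes(tree, gt, c(gx = 1e6, gy = 2e6))
  pc2 <- size_correct(pr, t_neq)
  expect_equal(unname(pc2$abundances[as.character(fx_id(tree, "s1"))]),
               2 / 3)
  expect_equal(unname(pc2$abundances[as.character(fx_id(tree, "s2"))]),
               1 / 3)

  # single-taxon profile unchanged
  pr1 <- profile_sample(votes[1], t_neq, ranks = "species")$species
  expect_equal(size_correct(pr1, t_neq)$abundances, pr1$abundances)

  # missing length errors with the taxa listed
  t_na <- set_genomes(tree, gt, c(gx = 1e6, gy = NA))
  expect_error(size_correct(pr, t_na), "no genome length")
})

test_that("CAMI profile output carries headers, paths and percentages", {
  tree <- fixture_tree()
  gt <- setNames(fx_id(tree, c("s1", "s2")), c("gx", "gy"))
  tree <- set_genomes(tree, gt, c(gx = 1e6, gy = 1e6))
  votes <- list(make_vote_table(tree, c(s1 = 0.6, s2 = 0.4)))
  prof <- profile_sample(votes, tree)
  path <- file.path(tempdir(), "prof.cami")
  on.exit(unlink(path), add = TRUE)
  write_cami_profile(prof, tree, path, sample_id = "S1")
  lines <- readLines(path)
  expect_equal(lines[1], "@SampleID:S1")
  expect_true(any(startsWith(lines, "@Ranks:superkingdom|")))
  body <- lines[!startsWith(lines, "@")]
  parts <- strsplit(body, "\t")
  expect_true(all(lengths(parts) == 5))
  # percentages at each rank sum to ~100
  by_rank <- split(as.numeric(sapply(parts, `[`, 5)),
                   sapply(parts, `[`, 2))
  for (v in by_rank) expect_equal(sum(v), 100, tolerance = 1e-6)
  # flat TSV mirror
  df <- profiles_to_df(prof, tree)
  expect_true(all(c("rank", "taxid", "name", "abundance") %in% names(df)))
})
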