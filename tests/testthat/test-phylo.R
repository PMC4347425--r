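test_that("pairwise identity follows the stated column conventions", {
  expect_equal(pairwise_identity_matrix(c(a = "MKVL", b = "MKVL"))[1, 2],
               100)
  m <- pairwise_identity_matrix(c(a = "ACDEFGHIK", b = "ACDEFGHIR"))
  expect_equal(m[1, 2], 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(m[2, 1], m[1, 2])
  expect_equal(diag(m), c(a = 100, b = 100))
  # terminal gaps are stripped; internal gap columns count against identity
  msa <- c(a = "--MKVLDE", b = "QTMKV-DE")
  expect_equal(pairwise_identity_matrix(msa, mode = "from_msa")[1, 2],
               100 * 5 / 6, tolerance = 1e-10)
  expect_error(pairwise_identity_matrix(c(a = "MK", a = "MK")),
               "duplicate")
  expect_error(pairwise_identity_matrix(c(a = "MK")), "at least two")
})

test_that("identity matrices are exactly symmetric on random families", {
  sim <- simulate_star_proteins(n_tips = 6, length_aa = 120, rate = 0.3,
                                seed = 9)
  m <- pairwise_identity_matrix(sim$prots)
  expect_identical(m, t(m))
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 100))
})

test_that("star-family identities match the closed-form expectation", {
  sim <- simulate_star_proteins(n_tips = 10, length_aa = 300, rate = 0.2,
                                seed = 5)
  m <- pairwise_identity_matrix(sim$prots, mode = "from_msa")
  off <- m[upper.tri(m)]
  expect_true(all(abs(off - sim$expected_identity_pct) <= 5))
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(d)
  # three-point formulas: a = (dab + dac - dbc)/2, etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[["a"]], 0.1, tolerance = 1e-10)
  expect_equal(lens[["b"]], 0.2, tolerance = 1e-10)
  expect_equal(lens[["c"]], 0.4, tolerance = 1e-10)
})

test_that("a clear quartet signal yields the ((a,b),(c,d)) topology", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.1
  tr <- build_nj_tree(d)
  ref <- ape::unroot(ape::read.tree(text = "((a,b),(c,d));"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ref)[[1]], 0)
})

test_that("NJ recovers the generating topology from additive distances", {
  withr::with_seed(2024, {
    for (i in 1:60) {
      ntax <- sample(6:12, 1)
      true <- ape::rtree(ntax, rooted = FALSE)
      true$edge.length <- runif(nrow(true$edge), 0.05, 0.5)
      dm <- ape::cophenetic.phylo(true)
      ord <- order(rownames(dm))
      dm <- dm[ord, ord]
      tr <- build_nj_tree(dm)
      expect_equal(ape::dist.topo(ape::unroot(tr), true)[[1]], 0)
    }
  })
})

test_that("malformed distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(build_nj_tree(d), "symmetric")
  d2 <- matrix(c(1, 0.2, 0.2, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(build_nj_tree(d2), "diagonal")
  expect_error(build_nj_tree(1:3), "square")
})

test_that("bootstrap supports are percentages of replicate bipartitions", {
  sim <- simulate_star_proteins(n_tips = 8, length_aa = 150, rate = 0.25,
                                seed = 13)
  one <- bootstrap_support(sim$prots, n_reps = 1, seed = 3)
  expect_true(all(as.numeric(one$node.label) %in% c(0, 100)))
  # identical seeds reproduce identical supports
  again <- bootstrap_support(sim$prots, n_reps = 1, seed = 3)
  expect_identical(ape::write.tree(one), ape::write.tree(again))
  expect_error(bootstrap_support(sim$prots, n_reps = 0), "at least 1")
})

test_that("a strong two-clade signal gets near-unit support", {
  a <- simulate_star_proteins(4, 200, 0.05, seed = 21)$prots
  b <- simulate_star_proteins(4, 200, 0.05, seed = 99)$prots
  names(b) <- sprintf("tipB%02d", seq_along(b))
  tr <- bootstrap_support(c(a, b), n_reps = 100, seed = 7)
  # the bipartition separating the two families must be near-certain
  expect_true(max(as.numeric(tr$node.label)) >= 95)
  split_node <- which(as.numeric(tr$node.label) >= 95)
  expect_true(length(split_node) >= 1)
})

test_that("trees and matrices round-trip through their text formats", {
  sim <- simulate_star_proteins(5, 80, 0.2, seed = 31)
  m <- pairwise_identity_matrix(sim$prots, mode = "from_msa")
  path <- tempfile(fileext = ".tsv")
  write_identity_matrix(m, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), m, ignore_attr = TRUE)
  tr <- build_nj_tree(identity_to_distance(m))
  np <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, np)
  back_tr <- ape::read.tree(np)
  expect_setequal(back_tr$tip.label, names(sim$prots))
})
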