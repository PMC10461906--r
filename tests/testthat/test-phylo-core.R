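test_that("read_newick parses, validates and resolves polytomies", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  tr2 <- read_newick("(A:1,B:1);")
  expect_equal(length(tr2$tip.label), 2L)

  # polytomy resolved into bifurcations with an inserted zero-length branch
  tp <- read_newick("((A:1,B:1,C:1):1,D:2);")
  expect_equal(length(tp$tip.label), 4L)
  expect_true(ape::is.binary(tp))
  expect_equal(tp$Nnode, 3L)
  expect_true(any(tp$edge.length == 0))
  # depths unchanged by resolution
  expect_equal(unname(ape::node.depth.edgelength(tp)[1:4]), rep(2, 4))

  expect_error(read_newick("((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(suppressWarnings(read_newick("not a tree")),
               "parse|Newick|unexpected")
})

test_that("write_newick round-trips branch lengths at full precision", {
  tr <- read_newick("(A:1,B:2);")
  back <- read_newick(write_newick(tr))
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  # rescaled (irrational) lengths survive serialisation
  tr$edge.length <- tr$edge.length * pi / 7
  back <- read_newick(write_newick(tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-12)

  expect_error(write_newick(NULL))
})

test_that("prune_tips collapses degree-2 nodes and preserves path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pr <- prune_tips(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(unname(ape::node.depth.edgelength(pr)[1:2]), c(2, 2))

  expect_equal(prune_tips(tr, c("A", "B", "C"))$Nnode, tr$Nnode)
  expect_error(prune_tips(tr, "A"), "at least 2")

  # pairwise tip-to-tip distances among kept tips are preserved exactly
  big <- random_ultrametric_tree(20, seed = 41)
  keep <- big$tip.label[c(1, 4, 7, 11, 15, 19)]
  d0 <- cophenetic(big)[keep, keep]
  d1 <- cophenetic(prune_tips(big, keep))[keep, keep]
  expect_equal(d1, d0)
})

test_that("is_ultrametric_tree applies a relative depth tolerance", {
  expect_true(is_ultrametric_tree(read_newick("((A:1,B:1):1,C:2);")))
  expect_false(is_ultrametric_tree(read_newick("(A:1,B:2);")))
  expect_true(is_ultrametric_tree(read_newick("(A:1.0,B:1.0005);"),
                                  rel_tol = 1e-3))
  expect_false(is_ultrametric_tree(read_newick("(A:1.0,B:1.0005);"),
                                   rel_tol = 1e-5))
})

test_that("pic_contrasts reproduces the hand-run recursion", {
  tr2 <- read_newick("(A:1,B:1);")
  cs <- pic_contrasts(tr2, c(A = 1, B = 0))
  expect_equal(abs(unname(cs$contrasts)), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(unname(cs$variances), 2)

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  cs3 <- pic_contrasts(tr3, c(A = 2, B = 0, C = 1))
  expect_equal(sort(abs(unname(cs3$contrasts))), c(0, sqrt(2)),
               tolerance = 1e-6)
  # second contrast joins the (A,B) estimate (extended branch 1.5) with C
  expect_setequal(unname(cs3$variances), c(3.5, 2))
  expect_equal(length(cs3$contrasts), 2L)  # n_tips - 1

  # all tips equal -> all contrasts zero
  cs0 <- pic_contrasts(tr3, c(A = 3, B = 3, C = 3))
  expect_equal(unname(cs0$contrasts), c(0, 0))

  expect_error(pic_contrasts(tr3, c(A = 1, B = 2)), "missing")
})

test_that("contrasts scale as 1/sqrt(c) under branch-length scaling", {
  tr <- random_ultrametric_tree(15, seed = 5)
  x <- named_trait(tr, rnorm(15))
  cs1 <- pic_contrasts(tr, x)
  for (cc in c(0.25, 7)) {
    trc <- tr
    trc$edge.length <- trc$edge.length * cc
    cs2 <- pic_contrasts(trc, x)
    expect_equal(cs2$contrasts, cs1$contrasts / sqrt(cc), tolerance = 1e-9)
    expect_equal(cs2$variances, cs1$variances * cc, tolerance = 1e-9)
  }
})

test_that("mean squared contrast is the REML rate, confirmed by grid search", {
  tr <- random_ultrametric_tree(5, seed = 9)
  set.seed(10)
  x <- named_trait(tr, as.numeric(simulate_traits(
    trait_params("BM", sigma2 = 1.3), tr)$values))
  cs <- pic_contrasts(tr, x)
  s2_reml <- mean(cs$contrasts^2)
  # REML likelihood of sigma2 given the (unstandardised) contrasts
  raw <- cs$contrasts * sqrt(cs$variances)
  reml_ll <- function(s2) sum(dnorm(raw, 0, sqrt(s2 * cs$variances),
                                    log = TRUE))
  grid <- seq(s2_reml * 0.2, s2_reml * 5, length.out = 20001)
  expect_equal(grid[which.max(vapply(grid, reml_ll, numeric(1)))], s2_reml,
               tolerance = 1e-3)
  expect_lte(reml_ll(s2_reml * 1.001), reml_ll(s2_reml))
  expect_lte(reml_ll(s2_reml * 0.999), reml_ll(s2_reml))
})

test_that("PIC variance matches the generating BM rate (Monte Carlo)", {
  tr <- random_ultrametric_tree(32, seed = 21)
  set.seed(22)
  sigma2 <- 1.7
  X <- simulate_traits(trait_params("BM", sigma2 = sigma2), tr, nsim = 1000)
  cs <- pic_contrasts(tr, X)
  expect_equal(mean(cs$contrasts^2), sigma2, tolerance = 0.05)
})

test_that("Blomberg's K is ~1 under BM and small for tree-free noise", {
  tr <- random_ultrametric_tree(200, seed = 31)
  set.seed(32)
  X <- simulate_traits(trait_params("BM", sigma2 = 1), tr, nsim = 500)
  ks <- vapply(seq_len(500), function(i)
    blomberg_k(tr, X[, i])$K, numeric(1))
  expect_equal(mean(ks), 1.0, tolerance = 0.1)

  set.seed(33)
  k_noise <- mean(vapply(1:25, function(i)
    blomberg_k(tr, named_trait(tr, rnorm(200)))$K, numeric(1)))
  expect_lt(k_noise, 0.3)

  # agreement with an established implementation on a single draw
  if (requireNamespace("phytools", quietly = TRUE)) {
    x <- X[, 1]
    expect_equal(blomberg_k(tr, x)$K,
                 unname(phytools::phylosig(tr, x, method = "K")[[1]]),
                 tolerance = 1e-6)
  }

  expect_false(blomberg_k(tr, named_trait(tr, rep(1, 200)))$valid)
  small <- read_newick("((A:1,B:1):1,C:2);")
  expect_false(blomberg_k(small, c(A = 1, B = 2, C = 3))$valid)
})
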