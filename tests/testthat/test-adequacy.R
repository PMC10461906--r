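mkcs <- function(contrasts, variances = rep(1, length(contrasts)),
                 heights = seq_along(contrasts) - 1,
                 ancestral = rep(0, length(contrasts)), depth = NULL) {
  if (is.null(depth)) depth <- max(heights, 1)
  structure(list(contrasts = contrasts, variances = variances,
                 node_heights = heights, ancestral = ancestral,
                 n_tips = length(contrasts) + 1L, depth = depth),
            class = "contrast_set")
}

test_that("unit-tree rescaling reproduces the model-implied variances", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  fitBM <- fit_trait_model("BM", tr, c(A = 0, B = 1, C = 3))
  fitBM$params$sigma2 <- 2
  ut <- make_unit_tree(tr, fitBM)
  expect_equal(sort(ut$tree$edge.length), sort(tr$edge.length * 2))

  # OU at vanishing alpha matches the BM rescaling
  fitOU <- fitBM
  fitOU$model <- "OU"
  fitOU$params <- trait_params("OU", sigma2 = 2, alpha = 1e-12, theta = 0)
  utOU <- make_unit_tree(tr, fitOU)
  expect_lt(max(abs(utOU$tree$edge.length - ut$tree$edge.length)), 1e-8)

  # per-tip root-to-tip length equals the covariance diagonal (all models,
  # random parameters, with measurement error)
  big <- random_ultrametric_tree(14, seed = 71)
  set.seed(72)
  for (m in c("BM", "OU", "EB")) for (i in 1:5) {
    p <- trait_params(m, sigma2 = runif(1, 0.1, 3),
                      alpha = runif(1, 0.1, 6), theta = 0,
                      r = runif(1, 0.1, 6), z0 = 0)
    se <- setNames(runif(14, 0, 0.7), big$tip.label)
    f <- structure(list(model = m, params = p, convergence = TRUE),
                   class = "model_fit")
    utm <- make_unit_tree(big, f, se)
    depths <- ape::node.depth.edgelength(utm$tree)[1:14]
    expect_equal(unname(depths),
                 unname(diag(model_covariance(p, big, se))),
                 tolerance = 1e-9)
  }

  bad <- fitBM; bad$convergence <- FALSE
  expect_error(make_unit_tree(tr, bad), "converge")
})

test_that("the five summary statistics match their closed forms", {
  expect_equal(stat_cvar(mkcs(c(1, 2, 3))), 0.5)
  expect_equal(stat_cvar(mkcs(c(1, 1, 1))), 0)
  expect_equal(stat_cvar(mkcs(c(1, -1, 1))), 0)
  expect_true(is.na(stat_cvar(mkcs(c(0, 0, 0)))))

  expect_equal(stat_dcdf(mkcs(0)), 0.5)
  expect_lte(stat_dcdf(mkcs(qnorm((1:99) / 100))), 0.02)
  expect_equal(stat_dcdf(mkcs(rep(10, 5))), 1, tolerance = 1e-6)
  set.seed(73)
  z <- rnorm(40)
  expect_equal(stat_dcdf(mkcs(z)),
               unname(suppressWarnings(ks.test(z, "pnorm"))$statistic),
               tolerance = 1e-12)

  expect_equal(stat_sasr(mkcs(c(1, 2), ancestral = c(0, 1))), 1)
  expect_equal(stat_sasr(mkcs(c(2, 2, 2), ancestral = c(0, 1, 3))), 0)
  expect_true(is.na(stat_sasr(mkcs(c(1, 2), ancestral = c(1, 1)))))

  expect_equal(stat_shgt(mkcs(c(1, 3), heights = c(0, 1))), 2)
  expect_equal(stat_shgt(mkcs(c(2, 2, 2), heights = c(0, 1, 2))), 0)
  degen <- mkcs(c(1, 3), heights = c(0.5, 0.5001), depth = 100)
  expect_true(is.na(stat_shgt(degen)))

  expect_equal(stat_svar(mkcs(c(1, 2), variances = c(1, 3))), 0.5)
  expect_true(is.na(stat_svar(mkcs(c(1, 2), variances = c(2, 2)))))

  all5 <- adequacy_stats(mkcs(c(1, 2, 3), variances = c(1, 2, 3),
                              heights = c(0, 1, 2),
                              ancestral = c(0, 1, 2)))
  expect_named(all5, c("c.var", "d.cdf", "s.asr", "s.hgt", "s.var"))
})

test_that("bootstrap_null draws calibrated BM(1) statistics, per seed", {
  tr <- random_ultrametric_tree(24, seed = 74)
  f <- structure(list(model = "BM",
                      params = trait_params("BM", sigma2 = 1.6),
                      convergence = TRUE), class = "model_fit")
  ut <- make_unit_tree(tr, f)
  b1 <- bootstrap_null(ut, n_sim = 200, seed = 75)
  b2 <- bootstrap_null(ut, n_sim = 200, seed = 75)
  expect_identical(b1$stats, b2$stats)
  expect_equal(dim(b1$stats), c(5L, 200L))

  # BM(1) on the unit tree: mean squared PIC about 1
  set.seed(76)
  X <- expadequacy:::simulate_bm_edges(ut$tree, 1000)
  cs <- pic_contrasts(ut$tree, X)
  expect_equal(mean(cs$contrasts^2), 1, tolerance = 0.02)
})

test_that("two-tailed Monte Carlo p-values follow the counting formula", {
  sims <- matrix(as.numeric(1:999), 1, dimnames = list("c.var", NULL))
  pv <- adequacy_pvalues(c(c.var = 500), sims)
  expect_equal(unname(pv$p_values), 1)

  pv2 <- adequacy_pvalues(c(c.var = 1e6), sims)
  expect_equal(unname(pv2$p_values), 0.002)
  expect_equal(unname(pv2$flags), "fail")

  pv3 <- adequacy_pvalues(c(s.hgt = NA_real_),
                          matrix(1:10, 1, dimnames = list("s.hgt", NULL)))
  expect_true(is.na(pv3$p_values))
  expect_true(is.na(pv3$flags))

  expect_gt(min(adequacy_pvalues(c(c.var = -5), sims)$p_values), 0)
})

test_that("node-height degeneracy yields NA under extreme OU, never under BM", {
  # all internal nodes deep in the tree: at the alpha bound nearly all unit
  # tree length sits on the terminal edges and node heights collapse
  tr <- read_newick(paste0(
    "(((t1:0.8,t2:0.8):0.1,(t3:0.8,t4:0.8):0.1):0.1,",
    "((t5:0.8,t6:0.8):0.1,(t7:0.8,t8:0.8):0.1):0.1);"))
  set.seed(78)
  # phylogeny-free noise forces alpha to the upper bound
  noise <- named_trait(tr, rnorm(8))
  fou <- fit_trait_model("OU", tr, noise)
  expect_gte(fou$params$alpha, 10)
  ad <- assess_adequacy(tr, noise, fou, n_sim = 200, seed = 79)
  expect_true(is.na(ad$observed[["s.hgt"]]))
  expect_true(is.na(ad$p_values[["s.hgt"]]))
  expect_true(is.na(ad$flags[["s.hgt"]]))
  expect_false(anyNA(ad$p_values[c("c.var", "d.cdf", "s.var")]))

  # BM fits on ordinary trees keep the node-height test defined
  for (i in 1:5) {
    trb <- random_ultrametric_tree(16, seed = 790 + i)
    x <- simulate_traits(trait_params("BM", sigma2 = 1), trb, seed = 80 + i)
    fb <- fit_trait_model("BM", trb, x)
    ut <- make_unit_tree(trb, fb)
    cs <- pic_contrasts(ut$tree, setNames(x$values, x$species))
    expect_false(is.na(stat_shgt(cs)))
  }
})

test_that("assess_adequacy composes the pipeline deterministically", {
  tr <- random_ultrametric_tree(32, seed = 81)
  tv <- simulate_traits(trait_params("BM", sigma2 = 1.2, z0 = 4), tr,
                        seed = 82)
  fit <- fit_trait_model("BM", tr, tv)
  a1 <- assess_adequacy(tr, tv, fit, n_sim = 150, seed = 83)
  a2 <- assess_adequacy(tr, tv, fit, n_sim = 150, seed = 83)
  expect_identical(a1$p_values, a2$p_values)
  expect_equal(a1$n_sim, 150)
  expect_true(all(a1$p_values > 0 & a1$p_values <= 1, na.rm = TRUE))
  expect_identical(unname(a1$flags[!is.na(a1$p_values)]),
                   unname(ifelse(a1$p_values[!is.na(a1$p_values)] < 0.05,
                                 "fail", "pass")))
})
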