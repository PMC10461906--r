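## Synthetic comparative expression data. The generator produces exactly the
## structure the pipeline consumes -- an ultrametric tree, a replicate-level
## linear-scale expression matrix with a sample sidecar, and a truth table --
## so every stage is testable without external datasets. Rate-shift genes
## violate all three fitted models and are labelled "none" in the truth
## table; no multi-rate model is ever fitted to them.

#' Simulate a pure-birth tree rescaled to unit depth
#'
#' @param n_species Number of tips (>= 4).
#' @param seed Optional integer seed.
#' @return An ultrametric `"phylo"` tree of depth 1.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 4) stop("need at least 4 species")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / tree_depth(tr)
  tr
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a typical published comparative expression set: a
#' modest number of species, a few replicates per species with log-scale
#' noise, some missing species per gene, and a minority of genes evolving
#' under a rate shift that none of the fitted models can capture. Shape
#' parameters are expressed as multiples of tree depth so the same
#' configuration works on any ultrametric tree.
#'
#' @param n_species Tips of the simulated tree.
#' @param n_genes Genes to generate.
#' @param model_mix Named proportions over `BM`, `OU`, `EB`, `shift`
#'   (must sum to 1).
#' @param sigma2_range Uniform range for the evolutionary rate (log-units^2
#'   per unit depth).
#' @param alpha_depth_range Uniform range for `alpha * depth` (OU genes).
#' @param r_depth_range Uniform range for `r * depth` (EB genes).
#' @param root_range Uniform range for the root state / OU optimum
#'   (log-expression units).
#' @param replicates Replicate samples per species.
#' @param noise_sd Replicate-level Gaussian noise sd on the log scale.
#' @param missing_frac Per-species probability that a gene lacks data for
#'   that species.
#' @param shift_multiplier Rate multiplier inside the shifted clade.
#' @param shift_clade_frac Approximate fraction of tips inside the shifted
#'   clade.
#' @param offset Pseudo-count used for the linear back-transform (must
#'   match the pipeline's log offset to round-trip).
#' @param seed Master seed.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n_species = 16, n_genes = 200,
                              model_mix = c(BM = 0.4, OU = 0.4, EB = 0.1,
                                            shift = 0.1),
                              sigma2_range = c(0.1, 2),
                              alpha_depth_range = c(0.5, 4),
                              r_depth_range = c(0.5, 4),
                              root_range = c(1, 6),
                              replicates = 3, noise_sd = 0.3,
                              missing_frac = 0.1, shift_multiplier = 10,
                              shift_clade_frac = 0.5, offset = 1, seed = 1) {
  stopifnot(all(c("BM", "OU", "EB", "shift") %in% names(model_mix)),
            abs(sum(model_mix) - 1) < 1e-9, all(model_mix >= 0),
            missing_frac >= 0, missing_frac < 1, replicates >= 1,
            noise_sd >= 0, shift_multiplier > 0)
  structure(as.list(environment()), class = "simulation_config")
}

## Internal-node set of the clade spanned by `tips` (MRCA and descendants).
clade_nodes <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("clade tips not in tree")
  if (length(idx) == ntip) stop("clade must be a proper subtree")
  if (length(idx) == 1L) return(idx)
  mrca <- ape::getMRCA(tree, idx)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  nodes <- mrca
  queue <- mrca
  while (length(queue)) {
    nxt <- unlist(kids[as.character(queue)], use.names = FALSE)
    nodes <- c(nodes, nxt)
    queue <- nxt[nxt > ntip]
  }
  in_clade <- tips_below(tree, mrca)
  if (!setequal(in_clade, tips))
    warning("tips do not form a monophyletic clade; using their MRCA clade")
  nodes
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  queue <- node
  while (length(queue)) {
    nxt <- unlist(kids[as.character(queue)], use.names = FALSE)
    out <- c(out, nxt[nxt <= ntip])
    queue <- nxt[nxt > ntip]
  }
  tree$tip.label[out]
}

#' Simulate one gene under a clade rate shift
#'
#' Brownian motion in which every branch inside the focal clade (its stem
#' edge included) runs at `sigma2 * multiplier` while the rest of the tree
#' runs at `sigma2`; drawn exactly from the implied covariance. This is the
#' "unmodeled rate heterogeneity" violation that none of BM/OU/EB can
#' absorb.
#'
#' @param tree An ultrametric `"phylo"` tree.
#' @param sigma2 Background rate (> 0).
#' @param multiplier Rate multiplier inside the clade (> 0); 1 recovers
#'   plain BM.
#' @param clade Character vector of tip labels spanning the clade (a proper
#'   subset of the tips).
#' @param z0 Root state.
#' @param seed Optional integer seed.
#' @return A [trait_vector()] of species means (se = 0).
#' @export
generate_rate_shift_gene <- function(tree, sigma2, multiplier, clade,
                                     z0 = 0, seed = NULL) {
  tree <- validate_tree(tree)
  stopifnot(sigma2 > 0, multiplier > 0)
  nodes <- clade_nodes(tree, clade)
  scaled <- tree
  hit <- tree$edge[, 2L] %in% nodes
  scaled$edge.length[hit] <- scaled$edge.length[hit] * multiplier
  if (!is.null(seed)) set.seed(seed)
  V <- sigma2 * ape::vcv.phylo(scaled)[tree$tip.label, tree$tip.label]
  L <- chol(V)
  x <- drop(crossprod(L, stats::rnorm(length(tree$tip.label)))) + z0
  trait_vector(setNames(x, tree$tip.label))
}

#' Generate a full synthetic comparative expression dataset
#'
#' Per gene: a model is drawn from `model_mix` and its parameters from the
#' configured ranges; species-level log means are simulated on the tree;
#' i.i.d. Gaussian replicate noise produces the replicate columns; the
#' configured fraction of species is blanked out (`NA`); and values are
#' back-transformed to the linear scale as `pmax(exp(x) - offset, 0)` so
#' the pipeline's log transform recovers the latent scale.
#'
#' @param config A [simulation_config()].
#' @param tree Optional tree to reuse; by default a fresh pure-birth tree
#'   of `config$n_species` tips is simulated from the master seed.
#' @return List with `tree`, `em` (an [expression_matrix()]), and `truth`
#'   (data frame: gene, model -- `"none"` for rate-shift genes -- sigma2,
#'   alpha, r, root, multiplier).
#' @export
generate_dataset <- function(config, tree = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(tree)) tree <- simulate_tree(config$n_species)
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  n <- length(tips)
  depth <- tree_depth(tree)

  ## fixed shifted clade: the internal node whose tip count is closest to
  ## shift_clade_frac * n (deterministic for a given tree)
  ntip <- n
  inner <- (ntip + 2L):(ntip + tree$Nnode)   # exclude the root
  sizes <- vapply(inner, function(nd) length(tips_below(tree, nd)), integer(1))
  target <- config$shift_clade_frac * n
  clade <- tips_below(tree, inner[which.min(abs(sizes - target))])

  runif1 <- function(r) stats::runif(1, r[1], r[2])
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  models <- sample(names(config$model_mix), config$n_genes, replace = TRUE,
                   prob = config$model_mix)
  truth <- data.frame(gene = gene_ids, model = models,
                      sigma2 = NA_real_, alpha = NA_real_, r = NA_real_,
                      root = NA_real_, multiplier = NA_real_,
                      stringsAsFactors = FALSE)
  truth$model[truth$model == "shift"] <- "none"

  nrep <- config$replicates
  samp <- data.frame(
    sample = paste0(rep(tips, each = nrep), "_r", seq_len(nrep)),
    species = rep(tips, each = nrep),
    replicate = rep(seq_len(nrep), times = n),
    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, config$n_genes, nrow(samp),
                 dimnames = list(gene_ids, samp$sample))

  for (i in seq_len(config$n_genes)) {
    s2 <- runif1(config$sigma2_range)
    root <- runif1(config$root_range)
    truth$sigma2[i] <- s2
    truth$root[i] <- root
    mu <- if (models[i] == "shift") {
      truth$multiplier[i] <- config$shift_multiplier
      generate_rate_shift_gene(tree, s2, config$shift_multiplier, clade,
                               z0 = root)
    } else {
      pars <- switch(models[i],
        BM = trait_params("BM", sigma2 = s2, z0 = root),
        OU = {
          a <- runif1(config$alpha_depth_range) / depth
          truth$alpha[i] <- a
          trait_params("OU", sigma2 = s2, alpha = a, theta = root)
        },
        EB = {
          r <- runif1(config$r_depth_range) / depth
          truth$r[i] <- r
          trait_params("EB", sigma2 = s2, r = r, z0 = root)
        })
      simulate_traits(pars, tree)
    }
    lat <- setNames(mu$values, mu$species)[tips]
    reps <- rep(lat, each = nrep) +
      stats::rnorm(n * nrep, sd = config$noise_sd)
    if (config$missing_frac > 0) {
      gone <- tips[stats::runif(n) < config$missing_frac]
      reps[samp$species %in% gone] <- NA_real_
    }
    vals[i, ] <- pmax(exp(reps) - config$offset, 0)
  }
  list(tree = tree, em = expression_matrix(vals, samp), truth = truth)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `tree.nwk`, `expression.tsv`, `samples.tsv` and `truth.tsv` under
#' `dir`; [read_expression()] and [read_newick()] read them back.
#'
#' @param ds A list from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(ds$tree, file.path(dir, "tree.nwk"))
  m <- data.frame(gene = rownames(ds$em$values), ds$em$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(m, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$em$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
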