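## Absolute (adequacy) assessment of a fitted model. The fitted parameters
## rescale the phylogeny into a "unit tree" on which, if the model is the
## generating process, the data behave as BM with rate 1 and the PICs are
## i.i.d. N(0,1). Five summary statistics of the contrasts are compared with
## their parametric-bootstrap distributions; two-tailed Monte Carlo p-values
## below the cutoff flag the model as inadequate for that gene.

STAT_NAMES <- c("c.var", "d.cdf", "s.asr", "s.hgt", "s.var")

#' Rescale a tree into a unit tree under a fitted model
#'
#' An edge running from height `t1` to height `t2` (root at 0, depth `T`)
#' receives length
#' \itemize{
#'   \item BM: `sigma2 * (t2 - t1)`
#'   \item OU: `sigma2 / (2 alpha) * (exp(-2 alpha (T - t2)) -
#'     exp(-2 alpha (T - t1)))`
#'   \item EB: `sigma2 * (exp(-r t1) - exp(-r t2)) / r`
#' }
#' (the OU/EB limits at vanishing shape reduce to BM), and each terminal
#' edge additionally gains the tip's `se^2`. The root-to-tip path length on
#' the unit tree then equals the model-implied trait variance of that tip.
#'
#' @param tree A `"phylo"` tree (ultrametric for OU/EB fits).
#' @param fit A converged `"model_fit"`.
#' @param se Per-species standard errors (named vector, [trait_vector()],
#'   or `NULL`).
#' @return A `"unit_tree"`: list with `tree` (rescaled `"phylo"`),
#'   `se_applied`, and `fit`.
#' @export
make_unit_tree <- function(tree, fit, se = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  if (!isTRUE(fit$convergence)) stop("fit did not converge")
  tree <- validate_tree(tree)
  p <- fit$params
  if (p$model != "BM" && !is_ultrametric_tree(tree))
    stop(p$model, " unit tree requires an ultrametric tree")
  h <- node_heights_all(tree)
  t1 <- h[tree$edge[, 1L]]
  t2 <- h[tree$edge[, 2L]]
  T <- max(h)
  s2 <- p$sigma2
  shape <- model_shape(p)
  el <- if (shape < TINY_SHAPE) s2 * (t2 - t1)
  else if (p$model == "OU")
    s2 / (2 * shape) * exp(-2 * shape * (T - t1)) * expm1(2 * shape * (t2 - t1))
  else s2 / shape * exp(-shape * t1) * -expm1(-shape * (t2 - t1))
  if (any(el < 0)) stop("negative rescaled branch length")
  sev <- aligned_se(se, tree$tip.label)
  term <- tree$edge[, 2L] <= length(tree$tip.label)
  el[term] <- el[term] + sev[tree$tip.label[tree$edge[term, 2L]]]^2
  ut <- tree
  ut$edge.length <- el
  structure(list(tree = ut, se_applied = any(sev > 0), fit = fit),
            class = "unit_tree")
}

## ---- the five summary statistics -------------------------------------

as_stat_matrix <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)

## OLS slope of each column of Y on a fixed predictor x (population moments).
slope_fixed <- function(x, Y) {
  sxx <- mean(x^2) - mean(x)^2
  (colMeans(x * Y) - mean(x) * colMeans(Y)) / sxx
}

## OLS slope of each column of Y on the matching column of X.
slope_paired <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  sxx <- colMeans(X^2) - mx^2
  b <- (colMeans(X * Y) - mx * my) / sxx
  b[sxx < 1e-18 * pmax(1, mx^2)] <- NA_real_
  b
}

drop1d <- function(v, was_vector) if (was_vector) v[[1L]] else v

#' Coefficient of variation of the absolute contrasts
#'
#' `sd(|PIC|) / mean(|PIC|)` (sample sd, n-1 denominator). Sensitive to
#' rate heterogeneity across the tree that the fitted model does not
#' capture.
#'
#' @param cs A `"contrast_set"` (contrasts may be a vector or a matrix with
#'   one column per simulated dataset).
#' @return Scalar (or one value per column). `NA` if `mean(|PIC|)` is 0.
#' @export
stat_cvar <- function(cs) {
  A <- abs(as_stat_matrix(cs$contrasts))
  n <- nrow(A)
  m <- colMeans(A)
  s <- sqrt(pmax(colSums(A^2) - n * m^2, 0) / (n - 1))
  out <- ifelse(m > 0, s / m, NA_real_)
  drop1d(out, !is.matrix(cs$contrasts))
}

ks_stat_norm <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x))
  i <- seq_len(n)
  max(pmax(abs(i / n - p), abs(p - (i - 1) / n)))
}

#' Kolmogorov-Smirnov distance of the contrasts from N(0,1)
#'
#' Sup-distance between the empirical CDF of the (signed) contrasts and the
#' standard normal CDF; detects departures from normality such as bursts of
#' change.
#'
#' @inheritParams stat_cvar
#' @return Scalar (or one value per column) in `[0, 1]`.
#' @export
stat_dcdf <- function(cs) {
  X <- as_stat_matrix(cs$contrasts)
  out <- apply(X, 2L, ks_stat_norm)
  drop1d(out, !is.matrix(cs$contrasts))
}

#' Slope of the absolute contrasts on the ancestral state estimates
#'
#' OLS slope of `|PIC|` on the nodal (ancestral) estimates; detects a
#' dependence of evolutionary rate on the trait value itself.
#'
#' @inheritParams stat_cvar
#' @return Scalar (or one value per column); `NA` when the ancestral
#'   estimates do not vary.
#' @export
stat_sasr <- function(cs) {
  Y <- abs(as_stat_matrix(cs$contrasts))
  X <- as_stat_matrix(cs$ancestral)
  drop1d(slope_paired(X, Y), !is.matrix(cs$contrasts))
}

#' Node-height test slope
#'
#' OLS slope of `|PIC|` on the root-to-node heights. On a unit tree from an
#' OU fit with very large `alpha`, nearly all variance sits on the terminal
#' edges and the node heights collapse to a point; the slope is then
#' unidentifiable and reported as `NA` (heights variance below
#' `1e-6 * depth^2`).
#'
#' @inheritParams stat_cvar
#' @return Scalar (or one value per column), possibly `NA`.
#' @export
stat_shgt <- function(cs) {
  h <- cs$node_heights
  if (stats::var(h) < 1e-6 * cs$depth^2)
    return(drop1d(rep(NA_real_, ncol(as_stat_matrix(cs$contrasts))),
                  !is.matrix(cs$contrasts)))
  Y <- abs(as_stat_matrix(cs$contrasts))
  drop1d(slope_fixed(h, Y), !is.matrix(cs$contrasts))
}

#' Slope of the absolute contrasts on their expected variances
#'
#' OLS slope of `|PIC|` on the contrasts' expected variances (the variances
#' themselves, not their square roots); picks up branch-length error in the
#' phylogeny.
#'
#' @inheritParams stat_cvar
#' @return Scalar (or one value per column); `NA` when the expected
#'   variances do not vary.
#' @export
stat_svar <- function(cs) {
  v <- cs$variances
  nc <- ncol(as_stat_matrix(cs$contrasts))
  if (stats::var(v) < 1e-16 * max(1, mean(v)^2))
    return(drop1d(rep(NA_real_, nc), !is.matrix(cs$contrasts)))
  Y <- abs(as_stat_matrix(cs$contrasts))
  drop1d(slope_fixed(v, Y), !is.matrix(cs$contrasts))
}

#' All five adequacy statistics at once
#'
#' @inheritParams stat_cvar
#' @return Named vector of the five statistics (`c.var`, `d.cdf`, `s.asr`,
#'   `s.hgt`, `s.var`), or a 5-row matrix with one column per simulated
#'   dataset.
#' @export
adequacy_stats <- function(cs) {
  vals <- list(stat_cvar(cs), stat_dcdf(cs), stat_sasr(cs),
               stat_shgt(cs), stat_svar(cs))
  if (is.matrix(cs$contrasts)) {
    out <- do.call(rbind, vals)
    rownames(out) <- STAT_NAMES
    out
  } else setNames(unlist(vals), STAT_NAMES)
}

#' Parametric-bootstrap null distributions of the adequacy statistics
#'
#' Simulates `n_sim` BM(rate 1, root 0) trait datasets on the unit tree,
#' pushes all of them through the contrast recursion in one vectorised
#' pass, and evaluates the five statistics on each.
#'
#' @param ut A `"unit_tree"` from [make_unit_tree()].
#' @param n_sim Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return List with `stats` (5 x `n_sim` matrix), `n_sim`, `seed`.
#' @export
bootstrap_null <- function(ut, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(ut, "unit_tree"), n_sim >= 2)
  if (!is.null(seed)) set.seed(seed)
  X <- simulate_bm_edges(ut$tree, n_sim)
  cs <- pic_contrasts(ut$tree, X)
  list(stats = adequacy_stats(cs), n_sim = n_sim, seed = seed)
}

#' Two-tailed Monte Carlo p-values for the adequacy statistics
#'
#' `p = 2 * min((1 + #\{sim <= obs\}) / (S + 1),
#' (1 + #\{sim >= obs\}) / (S + 1))`, capped at 1; the +1 pseudo-count keeps
#' Monte Carlo p-values strictly positive (conservative). `NA` simulated
#' values (the node-height degeneracy) are excluded; an `NA` observed
#' statistic gives an `NA` p-value and flag.
#'
#' @param observed Named vector of the five observed statistics.
#' @param sims 5 x S matrix of bootstrap statistics (rows as `observed`).
#' @param cutoff Rejection cutoff (default 0.05).
#' @return List with `p_values` and character `flags`
#'   (`"pass"`/`"fail"`/`NA`).
#' @export
adequacy_pvalues <- function(observed, sims, cutoff = 0.05) {
  p <- setNames(rep(NA_real_, length(observed)), names(observed))
  for (s in names(observed)) {
    obs <- observed[[s]]
    if (is.na(obs)) next
    sim <- sims[s, ]
    sim <- sim[!is.na(sim)]
    S <- length(sim)
    if (S == 0L) next
    p[s] <- min(1, 2 * min((1 + sum(sim <= obs)) / (S + 1),
                           (1 + sum(sim >= obs)) / (S + 1)))
  }
  flags <- ifelse(is.na(p), NA_character_, ifelse(p < cutoff, "fail", "pass"))
  list(p_values = p, flags = setNames(flags, names(observed)))
}

#' Assess the adequacy of a fitted model for one gene
#'
#' Composes the whole absolute-fit procedure: rescale the tree into a unit
#' tree with the fitted parameters (measurement error included), compute
#' the observed contrasts and the five statistics on the unit tree, build
#' their bootstrap null distributions, and derive two-tailed p-values.
#'
#' @param tree The original `"phylo"` tree.
#' @param trait A [trait_vector()] (or named vector) covering all tips.
#' @param fit A converged `"model_fit"` for these data.
#' @param n_sim Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param cutoff Rejection cutoff (default 0.05).
#' @return An `"adequacy_result"`: `observed`, `sim` (5 x `n_sim` matrix),
#'   `p_values`, `flags`, `msq_pic` (mean squared observed contrast on the
#'   unit tree), `contrasts`, `unit_tree`, `n_sim`, `seed`, `cutoff`.
#' @export
assess_adequacy <- function(tree, trait, fit, n_sim = 1000, seed = NULL,
                            cutoff = 0.05) {
  tree <- validate_tree(tree)
  trait <- as_trait_vector(trait)
  ut <- make_unit_tree(tree, fit, trait)
  cs <- pic_contrasts(ut$tree, setNames(trait$values, trait$species))
  observed <- adequacy_stats(cs)
  boot <- bootstrap_null(ut, n_sim = n_sim, seed = seed)
  pv <- adequacy_pvalues(observed, boot$stats, cutoff = cutoff)
  structure(list(observed = observed, sim = boot$stats,
                 p_values = pv$p_values, flags = pv$flags,
                 msq_pic = mean(cs$contrasts^2), contrasts = cs,
                 unit_tree = ut, n_sim = n_sim, seed = seed,
                 cutoff = cutoff),
            class = "adequacy_result")
}
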