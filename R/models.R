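## The three trait-evolution processes. Everything downstream (likelihood,
## simulation, unit-tree rescaling) is driven by the model-implied Gaussian
## covariance, so the processes are defined here once, in covariance form:
##   BM: cov(i,j) = sigma2 * t_shared
##   OU (root at the optimum, ultrametric depth T):
##       cov(i,j) = sigma2/(2 alpha) * exp(-2 alpha (T - t_shared)) *
##                  (1 - exp(-2 alpha t_shared))
##   EB: rate sigma2 * exp(-r t) integrated along shared history:
##       cov(i,j) = sigma2 * (1 - exp(-r t_shared)) / r   (t_shared as r -> 0)
## Fixed measurement error enters as se^2 on the diagonal and is never
## estimated.

TINY_SHAPE <- 1e-12  # below this, alpha/r are treated as the BM limit

#' Parameters of a trait-evolution process
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param sigma2 Evolutionary rate (trait variance per unit time, > 0). For
#'   EB this is the initial rate at the root.
#' @param alpha OU pull strength toward the optimum, per unit time (>= 0).
#' @param theta OU optimum, trait units. The root state is fixed at the
#'   optimum, so the OU mean vector is `theta`.
#' @param r EB decay rate of `sigma2` per unit time (>= 0); `r = 0` is BM.
#' @param z0 Root state (trait units) for BM and EB.
#' @return A `"trait_params"` list.
#' @export
trait_params <- function(model, sigma2, alpha = 0, theta = 0, r = 0, z0 = 0) {
  model <- match.arg(model, c("BM", "OU", "EB"))
  stopifnot(is.finite(sigma2), sigma2 > 0, alpha >= 0, r >= 0,
            is.finite(theta), is.finite(z0))
  structure(list(model = model, sigma2 = sigma2, alpha = alpha,
                 theta = theta, r = r, z0 = z0),
            class = "trait_params")
}

#' Species trait values with measurement error
#'
#' Holds the per-species (log-expression) means for one gene together with
#' the standard errors of those means. A missing/NULL `se` means error-free
#' observations.
#'
#' @param values Named numeric vector of species means (names = tip labels),
#'   or unnamed with `species` supplied.
#' @param se Standard errors (>= 0), recycled if length 1; `NULL` = 0.
#' @param species Optional character vector of species names.
#' @return A `"trait_vector"` list with `species`, `values`, `se`.
#' @export
trait_vector <- function(values, se = NULL, species = names(values)) {
  if (is.null(species)) stop("species names required")
  values <- as.numeric(values)
  if (length(species) != length(values)) stop("species/values length mismatch")
  if (anyDuplicated(species)) stop("duplicate species")
  if (any(!is.finite(values))) stop("trait values must be finite")
  if (is.null(se)) se <- 0
  se <- rep_len(as.numeric(se), length(values))
  if (any(!is.finite(se)) || any(se < 0)) stop("se must be finite and >= 0")
  structure(list(species = as.character(species), values = values, se = se),
            class = "trait_vector")
}

as_trait_vector <- function(trait, se = NULL) {
  if (inherits(trait, "trait_vector")) return(trait)
  trait_vector(trait, se = se)
}

## se aligned to the tree's tips, as a named vector (0 when absent).
aligned_se <- function(trait, tips) {
  se <- setNames(rep(0, length(tips)), tips)
  if (inherits(trait, "trait_vector")) {
    idx <- match(tips, trait$species)
    if (anyNA(idx)) stop("trait missing for tips: ",
                         paste(tips[is.na(idx)], collapse = ", "))
    se[] <- trait$se[idx]
  } else if (!is.null(trait)) {
    se[] <- rep_len(as.numeric(trait), length(tips))
  }
  se
}

## Unit-rate covariance (sigma2 = 1) from the shared-time matrix; the shape
## parameter is all that distinguishes the models here.
unit_covariance <- function(model, ts, T, shape) {
  switch(model,
    BM = ts,
    OU = if (shape < TINY_SHAPE) ts else
      exp(-2 * shape * (T - ts)) * -expm1(-2 * shape * ts) / (2 * shape),
    EB = if (shape < TINY_SHAPE) ts else -expm1(-shape * ts) / shape
  )
}

model_shape <- function(params)
  switch(params$model, BM = 0, OU = params$alpha, EB = params$r)

#' Model-implied covariance of species trait values
#'
#' @param params A [trait_params()] object.
#' @param tree A `"phylo"` tree; must be ultrametric (within the default
#'   tolerance of [is_ultrametric_tree()]) for OU and EB.
#' @param se Per-species standard errors: named vector, [trait_vector()],
#'   or `NULL`; `se^2` is added to the diagonal.
#' @return Symmetric positive semi-definite matrix, tips x tips, in the
#'   tree's tip order.
#' @export
model_covariance <- function(params, tree, se = NULL) {
  stopifnot(inherits(params, "trait_params"))
  tree <- validate_tree(tree)
  if (params$model != "BM" && !is_ultrametric_tree(tree))
    stop(params$model, " requires an ultrametric tree")
  ts <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  V <- params$sigma2 * unit_covariance(params$model, ts, max(diag(ts)),
                                       model_shape(params))
  sev <- aligned_se(se, tree$tip.label)
  diag(V) <- diag(V) + sev^2
  V
}

model_mean <- function(params, tips) {
  mu <- if (params$model == "OU") params$theta else params$z0
  setNames(rep(mu, length(tips)), tips)
}

## Dense multivariate-normal log density via Cholesky.
mvn_loglik <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("singular model covariance")
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Log-likelihood of trait values under a model
#'
#' Multivariate-normal log density of the species values with the
#' model-implied mean vector and [model_covariance()] (including the fixed
#' `se^2` diagonal term).
#'
#' @inheritParams model_covariance
#' @param trait Named numeric vector or [trait_vector()] covering all tips.
#' @return Log-likelihood (scalar).
#' @export
trait_loglik <- function(params, tree, trait) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  x <- trait_as_matrix(trait, tips)[, 1L]
  V <- model_covariance(params, tree,
                        if (inherits(trait, "trait_vector")) trait else NULL)
  mvn_loglik(x, model_mean(params, tips), V)
}

#' Simulate trait values under a model
#'
#' One exact multivariate-normal draw per replicate with the model mean and
#' covariance (measurement error included). Simulation is by covariance
#' draw, not path-wise integration: distributionally identical and
#' deterministic per seed.
#'
#' @inheritParams model_covariance
#' @param nsim Number of replicate draws.
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return For `nsim = 1` a [trait_vector()] (carrying `se`); otherwise a
#'   tips x `nsim` matrix of draws.
#' @export
simulate_traits <- function(params, tree, se = NULL, nsim = 1, seed = NULL) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  V <- model_covariance(params, tree, se)
  mu <- model_mean(params, tips)
  if (!is.null(seed)) set.seed(seed)
  ## chol of a PSD matrix with possible zero rows (sigma2 -> 0): add jitter-free
  ## pivoting via eigen fallback only when needed
  R <- tryCatch(chol(V), error = function(e) NULL)
  n <- length(tips)
  Z <- matrix(stats::rnorm(n * nsim), n, nsim)
  X <- if (!is.null(R)) crossprod(R, Z) else {
    e <- eigen(V, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    e$vectors %*% (sqrt(ev) * Z)
  }
  X <- X + mu
  rownames(X) <- tips
  if (nsim == 1L)
    trait_vector(setNames(X[, 1L], tips), se = aligned_se(se, tips))
  else X
}

## Fast BM(rate) simulation by independent normal increments along edges,
## all replicates at once. Used by the adequacy bootstrap where thousands of
## draws on the same (unit) tree are needed.
simulate_bm_edges <- function(tree, nsim, rate = 1, root = 0) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]
  sd_e <- sqrt(rate * tr$edge.length)
  X <- matrix(0, ntip + tree$Nnode, nsim)
  Z <- matrix(stats::rnorm(length(e1) * nsim), length(e1), nsim)
  for (i in seq_along(e1))
    X[e2[i], ] <- X[e1[i], ] + sd_e[i] * Z[i, ]
  X <- X[seq_len(ntip), , drop = FALSE] + root
  rownames(X) <- tr$tip.label
  X
}
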