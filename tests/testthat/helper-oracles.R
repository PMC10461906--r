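# Independent oracles used across the suite. These deliberately avoid the
# package's own computational routes: the MVN density goes through
# solve()/determinant() rather than the package's Cholesky path, and the
# shared-time matrix is taken from ape.

dense_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  d <- x - mu
  q <- drop(t(d) %*% solve(V, d))
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + q)
}

# Model covariances rebuilt from first principles on the shared-time matrix.
oracle_covariance <- function(model, tree, sigma2, alpha = 0, r = 0,
                              se = NULL) {
  ts <- ape::vcv.phylo(tree)
  T <- max(diag(ts))
  V <- switch(model,
    BM = sigma2 * ts,
    OU = sigma2 / (2 * alpha) * exp(-2 * alpha * (T - ts)) *
      (1 - exp(-2 * alpha * ts)),
    EB = if (r == 0) sigma2 * ts else sigma2 * (1 - exp(-r * ts)) / r)
  if (!is.null(se)) diag(V) <- diag(V) + se[rownames(ts)]^2
  V
}

random_ultrametric_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

named_trait <- function(tree, values) setNames(values, tree$tip.label)
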