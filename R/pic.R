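## Phylogenetic independent contrasts (Felsenstein's pruning recursion) and
## Blomberg's K. The recursion is written to accept a matrix of trait vectors
## (tips x replicates) and process all columns at once; the adequacy bootstrap
## pushes hundreds of simulated genes through it in a single pass.

#' Phylogenetic independent contrasts
#'
#' Runs the pruning recursion on a bifurcating tree: at each internal node
#' joining child estimates `x1`, `x2` with (extended) branch lengths `v1`,
#' `v2`, the contrast is `(x1 - x2) / sqrt(v1 + v2)` with expected variance
#' `v1 + v2`; the nodal estimate is the weighted average
#' `(x1/v1 + x2/v2) / (1/v1 + 1/v2)` and the parent branch is extended by
#' `v1 * v2 / (v1 + v2)`. Zero-length branches are floored at
#' `1e-8 * depth` so the recursion stays defined after polytomy resolution.
#'
#' @param tree A bifurcating `"phylo"` tree.
#' @param trait Named numeric vector (names = tip labels), a
#'   [trait_vector()], or a numeric matrix with one row per tip (rownames =
#'   tip labels) and one column per replicate dataset.
#' @return A `"contrast_set"`: list with `contrasts` and `ancestral`
#'   (vector, or matrix with one column per input column), `variances`
#'   (expected variance of each contrast), `node_heights` (root-to-node
#'   distances), `n_tips`, and `depth`. Entries are indexed by internal
#'   node id; the root comes first.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 2, B = 0, C = 1))
#' @export
pic_contrasts <- function(tree, trait) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  nnode <- tree$Nnode

  X <- trait_as_matrix(trait, tips)
  was_vector <- ncol(X) == 1L && (!is.matrix(trait) || ncol(trait) == 1L)

  depth <- tree_depth(tree)
  if (depth <= 0) stop("tree has zero depth")
  heights <- node_heights_all(tree)

  tr <- ape::reorder.phylo(tree, "postorder")
  e1 <- tr$edge[, 1L]
  e2 <- tr$edge[, 2L]
  el <- tr$edge.length
  el[el <= 0] <- 1e-8 * depth

  nc <- ncol(X)
  val <- matrix(0, ntip + nnode, nc)
  val[seq_len(ntip), ] <- X
  vx <- numeric(ntip + nnode)           # extra variance from descendants
  contrasts <- matrix(NA_real_, nnode, nc)
  variances <- numeric(nnode)

  for (i in seq(1L, length(e1), by = 2L)) {
    node <- e1[i]
    if (e1[i + 1L] != node) stop("tree is not bifurcating")
    c1 <- e2[i]; c2 <- e2[i + 1L]
    v1 <- el[i] + vx[c1]
    v2 <- el[i + 1L] + vx[c2]
    vs <- v1 + v2
    if (vs <= 0) stop("zero combined branch variance at node ", node)
    j <- node - ntip
    contrasts[j, ] <- (val[c1, ] - val[c2, ]) / sqrt(vs)
    variances[j] <- vs
    val[node, ] <- (val[c1, ] / v1 + val[c2, ] / v2) / (1 / v1 + 1 / v2)
    vx[node] <- v1 * v2 / vs
  }

  ids <- as.character(ntip + seq_len(nnode))
  anc <- val[ntip + seq_len(nnode), , drop = FALSE]
  rownames(contrasts) <- rownames(anc) <- ids
  structure(list(
    contrasts    = if (was_vector) contrasts[, 1L] else contrasts,
    variances    = setNames(variances, ids),
    node_heights = setNames(heights[ntip + seq_len(nnode)], ids),
    ancestral    = if (was_vector) anc[, 1L] else anc,
    n_tips       = ntip,
    depth        = depth
  ), class = "contrast_set")
}

## Coerce the accepted trait representations to a tips x replicates matrix
## in the tree's tip order, failing on missing species.
trait_as_matrix <- function(trait, tips) {
  if (inherits(trait, "trait_vector"))
    trait <- setNames(trait$values, trait$species)
  if (is.matrix(trait)) {
    if (is.null(rownames(trait))) stop("trait matrix needs tip rownames")
    miss <- setdiff(tips, rownames(trait))
    if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
    X <- trait[tips, , drop = FALSE]
  } else {
    if (is.null(names(trait))) stop("trait vector needs tip names")
    miss <- setdiff(tips, names(trait))
    if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
    X <- matrix(trait[tips], ncol = 1L, dimnames = list(tips, NULL))
  }
  if (anyNA(X) || any(!is.finite(X))) stop("trait values must be finite")
  X
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Ratio of the observed mean squared error of the data around the
#' phylogenetic (GLS) mean to the mean squared error under the tree's
#' Brownian covariance, divided by its Brownian-motion expectation.
#' K is about 1 for traits evolving by BM on the tree and much smaller for
#' traits that ignore the phylogeny.
#'
#' @param tree A `"phylo"` tree with at least 4 tips.
#' @param trait Named numeric vector or [trait_vector()].
#' @return A `"signal_result"`: list with `K` and `valid`. `valid` is
#'   `FALSE` (with `K = NA`) for degenerate input: fewer than 4 tips or a
#'   constant trait.
#' @export
blomberg_k <- function(tree, trait) {
  tree <- validate_tree(tree)
  out <- function(K, valid) structure(list(K = K, valid = valid),
                                      class = "signal_result")
  n <- length(tree$tip.label)
  if (n < 4L) return(out(NA_real_, FALSE))
  x <- trait_as_matrix(trait, tree$tip.label)[, 1L]
  if (stats::var(x) == 0) return(out(NA_real_, FALSE))
  C <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  Ci <- solve(C)
  ahat <- sum(Ci %*% x) / sum(Ci)
  res <- x - ahat
  mse0 <- sum(res^2) / (n - 1)
  mse <- drop(res %*% Ci %*% res) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  out((mse0 / mse) / expected, TRUE)
}
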