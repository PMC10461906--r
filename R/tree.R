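## Tree handling. The container is ape's "phylo"; every tree entering the
## model-fitting layer is validated and made strictly bifurcating first.

#' Read a Newick tree and prepare it for comparative analysis
#'
#' Parses a Newick string (or file), checks that every non-root edge carries a
#' branch length and that tip labels are unique, and resolves polytomies
#' deterministically (left-to-right, `ape::multi2di(random = FALSE)`) into
#' zero-length bifurcations so the contrast recursion is defined everywhere.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a Newick file.
#' @return An object of class `"phylo"`, rooted and strictly bifurcating.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tr <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("Newick parse failure")
  validate_tree(tr)
}

#' Serialise a tree to Newick
#'
#' Branch lengths are written with full precision so that a
#' [read_newick()] round trip reproduces them within 1e-9.
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) == 0L)
    stop("not a valid tree")
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## Validation used by read_newick and by every entry point taking a tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch length on an edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}

#' Prune a tree down to a set of tips
#'
#' Drops all tips not in `keep`; degree-2 nodes created by the removal are
#' collapsed with their branch lengths summed, so root-to-tip depths of the
#' retained tips are unchanged. Used to excise species with no expression
#' data for a gene before fitting.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` tree.
#' @export
prune_tips <- function(tree, keep) {
  tree <- validate_tree(tree)
  keep <- unique(as.character(keep))
  bad <- setdiff(keep, tree$tip.label)
  if (length(bad))
    stop("tips not in tree: ", paste(bad, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within `rel_tol` of the maximum
#' depth. The default tolerance absorbs the numerical noise typical of
#' time-calibrated chronograms.
#'
#' @param tree A `"phylo"` object.
#' @param rel_tol Relative tolerance (fraction of the maximum depth).
#' @return Logical flag.
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-3) {
  tree <- validate_tree(tree)
  d <- tip_depths(tree)
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) <= rel_tol * mx
}

## Distance from the root for every node (tips first, ape numbering).
node_heights_all <- function(tree) ape::node.depth.edgelength(tree)

tip_depths <- function(tree) {
  node_heights_all(tree)[seq_along(tree$tip.label)]
}

tree_depth <- function(tree) max(tip_depths(tree))
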