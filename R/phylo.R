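#' Parse a Newick tree with validation
#'
#' Reads a Newick string or file via \pkg{ape} and enforces the contract the
#' downstream distance computation needs: unique leaf labels, a branch
#' length on every edge, and no negative lengths. Internal node labels are
#' ignored.
#'
#' @param text A Newick string, or a path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- if (length(text) == 1L && file.exists(text))
    ape::read.tree(text)
  else
    ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("every edge must carry a branch length")
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tr
}

#' Pairwise patristic distances between leaves
#'
#' Sum of branch lengths along the unique path between every pair of leaves,
#' in the tree's own branch-length units. Patristic distance does not depend
#' on the root position.
#'
#' @param tree An `ape::phylo` tree (e.g. from [parse_newick()]).
#' @return A `distance_matrix`: list with `strains` (leaf labels in tree
#'   order) and `d`, a symmetric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- stats::cophenetic(tree)
  labs <- tree$tip.label
  d <- d[labs, labs]
  structure(list(strains = labs, d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d leaves, max distance %.4g\n",
              length(x$strains), max(x$d)))
  invisible(x)
}
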