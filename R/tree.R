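#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei Q-criterion with the standard
#' branch-length formulas, via [ape::nj()]). Negative branch-length
#' estimates, which NJ can produce on non-additive matrices, are clamped to
#' zero and flagged through the `"clamped"` attribute.
#'
#' @param distance_matrix Symmetric numeric matrix with zero diagonal and
#'   taxon labels as dimnames; at least 3 taxa. The typical input here is
#'   `1 - identity_fraction` from [all_vs_all()].
#' @return An [ape::as.phylo] object (unrooted, leaves = taxa) with
#'   attribute `clamped` (TRUE if any branch length was negative).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)$edge.length  # 1, 1, 3 up to edge order
#' @export
neighbor_joining <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tree <- ape::nj(d)
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are written with 6 significant digits; labels containing
#' Newick metacharacters are quoted by ape.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return Newick text (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Leaf partition induced by removing the tree's longest internal edge
#'
#' Utility for qualitative clade tests: splits the unrooted tree at its
#' deepest internal bipartition (the edge with the largest length among
#' internal edges) and returns the two leaf sets.
#'
#' @param tree A `phylo` object.
#' @return A list of two character vectors of leaf labels.
#' @export
tree_bipartition <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (!length(internal)) stop("tree has no internal edge")
  e <- internal[which.max(tree$edge.length[internal])]
  child <- tree$edge[e, 2]
  # leaves reachable below `child` without crossing the chosen edge
  stack <- child
  tips <- integer(0)
  while (length(stack)) {
    node <- stack[1]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  below <- tree$tip.label[sort(tips)]
  list(below, setdiff(tree$tip.label, below))
}
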