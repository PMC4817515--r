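# Neighbor-joining trees and rooting.
#
# NJ itself is the canonical saitou-nei algorithm as implemented in ape;
# this layer adds validation, deterministic input ordering, clamping of the
# (rare) negative branch lengths, and rooting by outgroup or midpoint.

#' Neighbor-joining tree from a distance matrix
#'
#' @param dm symmetric distance matrix with genome ids as dimnames (>= 3
#'   taxa). Additive inputs are reconstructed exactly (topology and branch
#'   lengths).
#' @return an unrooted ape `phylo`. Negative branch lengths, which NJ can
#'   produce on non-additive inputs, are clamped to 0 with a warning.
#' @export
neighbor_joining <- function(dm) {
  dm <- validate_dm(as.matrix(dm))
  if (nrow(dm) < 3) stop_param("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a tree by outgroup or at the midpoint
#'
#' @param tree an ape `phylo`.
#' @param outgroup a tip label; when `NULL`, midpoint rooting is used.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL) {
  if (is.null(outgroup)) {
    return(phangorn::midpoint(tree))
  }
  if (!outgroup %in% tree$tip.label) {
    stop_input("outgroup '%s' is not a tip of the tree", outgroup)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
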