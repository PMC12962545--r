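# Tree utilities: patristic distances and the phylogenetic covariance matrix
# consumed by the phylogenetic mixed models and the feedback analyses.

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between each pair of tips.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = tip
#'   labels.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_mf("tree has no branch lengths; patristic distances are undefined")
  if (any(tree$edge.length < 0))
    stop_mf("tree has negative branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Phylogenetic (Brownian-motion) covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j, rescaled so that the mean diagonal
#' element equals 1.  Under Brownian motion on the tree this is the
#' covariance (up to the rate) of a trait among tips; for an ultrametric
#' tree the diagonal is constant.  The mean-diagonal-1 scaling makes the
#' phylogenetic variance component of a mixed model interpretable on the
#' response scale and comparable across trees.
#'
#' @inheritParams patristic_distances
#' @param scale logical; rescale to mean diagonal 1 (default `TRUE`).
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, scale = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_mf("tree has no branch lengths; covariance is undefined")
  # an unrooted binary tree (ape stores it as a basal trifurcation with
  # Ntip - 2 internal nodes) has no defined root height; a genuine basal
  # polytomy (e.g., a star tree) is fine
  if (!ape::is.rooted(tree) && tree$Nnode == length(tree$tip.label) - 2L)
    stop_mf("tree is unrooted; root it first (e.g., midpoint rooting)")
  C <- ape::vcv.phylo(tree)
  C <- C[tree$tip.label, tree$tip.label]
  if (scale) C <- C / mean(diag(C))
  C
}
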