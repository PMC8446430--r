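#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering of profiles on the distance scale
#' `1 - similarity`, so merge heights live in \[0, 1\]. Average linkage is the
#' default; input order and the stable agglomeration of [stats::hclust()]
#' make the result deterministic.
#'
#' @param sm a [similarity_matrix()] (symmetric, unit diagonal).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An object of class `cluster_tree`: list with the `hclust` fit
#'   (`hc`), `labels`, and `linkage`.
#' @export
cluster_profiles <- function(sm, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(sm, "similarity_matrix"))
  v <- sm$values
  if (!isSymmetric(unname(v), tol = 1e-8)) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  d <- as.dist(1 - v)
  hc <- hclust(d, method = linkage)
  structure(list(hc = hc, labels = sm$labels, linkage = linkage),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree>", length(x$labels), "leaves,", x$linkage, "linkage\n")
  invisible(x)
}

#' Cut a cluster tree into k clades
#' @param tree a [cluster_profiles()] result.
#' @param k number of clades.
#' @return Named integer vector of clade memberships.
#' @export
cut_clades <- function(tree, k = 2) {
  stopifnot(inherits(tree, "cluster_tree"))
  cutree(tree$hc, k = k)
}

#' Export a cluster tree as Newick
#'
#' Converts the dendrogram to a phylogenetic tree (branch lengths derived
#' from merge heights, so a two-leaf tree merged at height h gets two
#' branches of h/2) and writes standard re-parseable Newick.
#'
#' @param tree a [cluster_profiles()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Fraction of controls falling in the control-majority clade
#'
#' Convenience summary for case/control segregation: cuts the tree into two
#' clades and reports the share of control profiles inside whichever clade
#' holds the majority of controls.
#'
#' @param tree a [cluster_profiles()] result.
#' @param control_labels labels of the control profiles.
#' @return A number in \[0, 1\].
#' @export
control_clade_purity <- function(tree, control_labels) {
  cl <- cut_clades(tree, k = 2)
  ctrl <- cl[names(cl) %in% control_labels]
  if (!length(ctrl)) stop("no control labels found in tree", call. = FALSE)
  max(table(ctrl)) / length(ctrl)
}
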