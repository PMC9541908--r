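#' Set every branch length to one
#'
#' Supertrees assembled from taxonomy lack meaningful branch lengths; the
#' first step towards the species correlation matrix is to discard whatever
#' lengths are present and set every edge to 1. Idempotent.
#'
#' @param tree An \code{ape} \code{phylo} object.
#' @return The tree with all edge lengths equal to 1.
#' @export
unit_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Make a tree ultrametric by Grafen's method
#'
#' Each internal node's height is set to (number of descendant tips - 1),
#' normalised by (total tips - 1), raised to the power \code{rho}; tips sit
#' at height 0 and branch lengths are recomputed from the heights, so every
#' root-to-tip distance equals 1.
#'
#' @param tree A rooted \code{phylo} object.
#' @param rho Power applied to the normalised node heights (default 1).
#' @return An ultrametric tree of depth 1.
#' @export
grafen_transform <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Species correlation matrix from an ultrametric tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j
#' divided by the tree depth, so the diagonal is exactly 1 and the matrix is
#' positive semi-definite (it is a Gram matrix of shared evolutionary
#' history). This matrix specifies the correlation of species-level effects
#' in the meta-analytic model.
#'
#' @param tree Ultrametric \code{phylo} object (see
#'   \code{\link{grafen_transform}}).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return A symmetric correlation matrix with species labels as dimnames.
#' @export
vcv_from_tree <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) > 1 &&
      !ape::is.ultrametric(tree, tol = tol, option = 2)) {
    stop("tree is not ultrametric; apply grafen_transform() first")
  }
  if (length(tree$tip.label) == 1) {
    return(matrix(1, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  v <- ape::vcv(tree)
  a <- v / mean(diag(v))
  diag(a) <- 1
  a
}

#' Prune a tree to a species subset
#'
#' Induced subtree on \code{keep}: all other tips are dropped and resulting
#' degree-2 internal nodes are collapsed with their branch lengths summed,
#' so shared path lengths among the kept species are preserved.
#'
#' @param tree A \code{phylo} object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned tree (a bare one-tip stub when \code{length(keep) == 1}).
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) == 1) {
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = keep, edge.length = 1, Nnode = 1L),
                     class = "phylo"))
  }
  ape::keep.tip(tree, keep)
}

#' Attach species as a polytomy at the base of a clade
#'
#' Adds each new tip as a direct child of the most recent common ancestor
#' of \code{at_clade}, turning that node into a polytomy. Used for species
#' whose placement is known only to clade level. Branch lengths are
#' arbitrary afterwards: re-apply \code{\link{unit_branch_lengths}} and
#' \code{\link{grafen_transform}} before building a correlation matrix.
#'
#' @param tree A \code{phylo} object.
#' @param new_species Character vector of tip labels to add.
#' @param at_clade Character vector of existing tip labels that must form a
#'   monophyletic group; the new tips are attached at its stem node.
#' @return The enlarged tree.
#' @export
attach_polytomy <- function(tree, new_species, at_clade) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(at_clade %in% tree$tip.label)) stop("at_clade contains unknown tips")
  if (any(new_species %in% tree$tip.label)) stop("new species already in tree")
  if (length(at_clade) == 1) {
    node <- match(at_clade, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, at_clade)
    desc <- ape::extract.clade(tree, node)$tip.label
    if (!setequal(desc, at_clade)) {
      stop("at_clade is not monophyletic (MRCA also subtends: ",
           paste(setdiff(desc, at_clade), collapse = ", "), ")")
    }
  }
  for (sp in new_species) {
    if (is.null(tree$edge.length)) tree <- unit_branch_lengths(tree)
    tree <- phytools::bind.tip(tree, sp, edge.length = 1, where = node,
                               position = 0)
    # node ids shift after binding; relocate the clade's MRCA
    node <- if (length(at_clade) == 1) {
      tgt <- ape::getMRCA(tree, c(at_clade, sp))
      tgt
    } else {
      ape::getMRCA(tree, at_clade)
    }
  }
  tree
}

#' Write a species correlation matrix as delimited text
#'
#' @param mat Correlation matrix with species dimnames.
#' @param path Output CSV path (labels as header row and first column).
#' @export
write_vcv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
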