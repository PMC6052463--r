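#' Tree utilities
#'
#' Small helpers around `ape::phylo` objects used throughout the package.
#' Trees are rooted with branch lengths in million years (My); most analyses
#' additionally assume ultrametry (every root-to-tip path has the same
#' length, the tree depth T).
#'
#' @name tree-utils
NULL

#' Depth of a rooted tree
#'
#' Maximum root-to-tip path length, in the units of the branch lengths.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return numeric scalar.
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  max(ape::node.depth.edgelength(tree))
}

#' Shared-path matrix
#'
#' For tips i and j, the length of the path from the root to their most
#' recent common ancestor. This is the Brownian-motion covariance structure
#' (up to the rate), with diagonal equal to the root-to-tip path lengths.
#'
#' @param tree a rooted `phylo` object.
#' @return species x species numeric matrix with tip labels as dimnames.
#' @export
shared_path_matrix <- function(tree) {
  ape::vcv(tree)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips. For an
#' ultrametric tree of depth T, `d_ij = 2 * (T - t_ij)` where `t_ij` is the
#' shared path length.
#'
#' @param tree a rooted `phylo` object.
#' @return species x species numeric matrix.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

#' Age of the most recent common ancestor for each tip pair
#'
#' On an ultrametric, time-calibrated tree this is the divergence time of
#' the pair: `T - t_ij`, zero on the diagonal.
#'
#' @param tree a rooted, ultrametric `phylo` object.
#' @return species x species numeric matrix of ages (My).
#' @export
mrca_age_matrix <- function(tree) {
  V <- shared_path_matrix(tree)
  T <- max(diag(V))
  A <- T - V
  diag(A) <- 0
  A
}

#' Collapse zero-length internal branches
#'
#' Zero-length branches create duplicate rows in phylogenetic covariance
#' matrices; collapsing them into polytomies keeps the matrices positive
#' definite.
#'
#' @param tree a `phylo` object.
#' @param tol branches shorter than this are collapsed.
#' @return a `phylo` object.
#' @export
collapse_zero_branches <- function(tree, tol = 1e-10) {
  ape::di2multi(tree, tol = tol)
}

#' Packaged 14-species Drosophila fixture tree
#'
#' A rooted ultrametric 14-taxon tree with 56 My root depth, matching the
#' classical two-subgenus structure of the genus: subgenus *Drosophila*
#' (Dvir, Dmoj; the virilis-repleta radiation) versus subgenus *Sophophora*,
#' the latter containing the willistoni (Dwil) and saltans (Dsal, Daus)
#' groups and a nine-species melanogaster group clade (Dana, Dbip, Dkik,
#' Dbia, Dyak, Dere, Dmel, Dsim, Dsec). Internal node ages are round-number
#' calibrations consistent with published divergence-time estimates for the
#' genus; they are intended as a realistic simulation scaffold, not as a new
#' dating analysis.
#'
#' @return a `phylo` object with 14 tips.
#' @seealso [drosophila_groups()] for the taxonomic grouping of the tips.
#' @export
drosophila_tree <- function() {
  path <- system.file("extdata", "drosophila_14sp_56my.nwk",
                      package = "longsig", mustWork = TRUE)
  ape::read.tree(path)
}

#' Taxonomic grouping of the fixture tree tips
#'
#' @return data.frame with columns `species`, `subgenus`, `species_group`.
#' @export
drosophila_groups <- function() {
  path <- system.file("extdata", "drosophila_groups.tsv",
                      package = "longsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Tip sets subtended by every edge, as indices into tree$tip.label.
# Internal helper shared by the bootstrap-support and regime-painting code.
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]
    chi <- post$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  # return one set per edge of the *original* edge matrix (child side)
  lapply(seq_len(nrow(tree$edge)), function(k) sort(sets[[tree$edge[k, 2L]]]))
}

# Canonical bipartition keys for the internal edges of an (unrooted or
# rooted) tree: each internal edge splits the tips in two; the key is the
# sorted label set of the side NOT containing the alphabetically first tip.
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  nt <- length(labs)
  anchor <- labs[order(labs)][1L]
  sets <- edge_tip_sets(tree)
  keys <- character(0)
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (length(s) <= 1L || length(s) >= nt - 1L) next  # trivial split
    side <- labs[s]
    if (anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}
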