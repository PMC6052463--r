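#' Expression distance between species
#'
#' Dissimilarity `1 - rho` where `rho` is the Spearman rank correlation of
#' the two species' expression profiles across genes (average ranks for
#' ties). Values lie in `[0, 2]`.
#'
#' @param e expression matrix, genes x species (>= 2 genes, >= 3 species).
#' @return symmetric species x species matrix with zero diagonal and a
#'   `metric` attribute `"one-minus-spearman"`.
#' @export
expression_distance <- function(e) {
  v <- as.matrix(e)
  if (ncol(v) < 3) stop("need at least 3 species", call. = FALSE)
  if (nrow(v) < 2) stop("need at least 2 genes", call. = FALSE)
  const <- apply(v, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant expression column(s): ",
         paste(colnames(v)[const], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(v, method = "spearman")
  diag(d) <- 0
  attr(d, "metric") <- "one-minus-spearman"
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]), post-processed
#' so that negative branch lengths are clamped to zero with the deficit
#' moved to a sibling edge (preserving path lengths through the joined
#' node), the usual convention for distance trees shown with nonnegative
#' branches.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @return an unrooted `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (k in neg) {
    deficit <- tr$edge.length[k]
    tr$edge.length[k] <- 0
    sib <- setdiff(which(tr$edge[, 1L] == tr$edge[k, 1L]), k)
    if (length(sib))
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Expression phylogram with gene-bootstrap branch support
#'
#' Builds the neighbor-joining phylogram from the expression distance
#' matrix, then resamples genes with replacement `B` times, rebuilding the
#' distances and the tree each time. The support of an internal edge is the
#' fraction of replicates whose tree contains the same bipartition of the
#' taxa (branch lengths ignored). Optionally roots the result on a named
#' outgroup.
#'
#' @param e expression matrix, genes x species.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling (optional).
#' @param outgroup optional tip label to root the phylogram on.
#' @return list of class `phylogram_result`: `tree` (with supports as
#'   internal node labels), `support` (named by bipartition key),
#'   `distances`, `B`.
#' @export
bootstrap_support <- function(e, B = 1000, seed = NULL, outgroup = NULL) {
  v <- as.matrix(e)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(outgroup) && !(outgroup %in% colnames(v)))
    stop("outgroup not among the species", call. = FALSE)
  d <- expression_distance(v)
  ref <- neighbor_joining(d)
  keys <- bipartition_keys(ref)
  hits <- stats::setNames(numeric(length(keys)), keys)
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(v)
  for (b in seq_len(B)) {
    idx <- sample.int(ng, ng, replace = TRUE)
    db <- 1 - stats::cor(v[idx, , drop = FALSE], method = "spearman")
    diag(db) <- 0
    kb <- bipartition_keys(neighbor_joining(db))
    m <- keys %in% kb
    hits[m] <- hits[m] + 1
  }
  support <- hits / B
  out_tree <- ref
  if (!is.null(outgroup))
    out_tree <- ape::root(ref, outgroup = outgroup, resolve.root = TRUE)
  out_tree <- label_supports(out_tree, support)
  structure(list(tree = out_tree, support = support, distances = d, B = B),
            class = "phylogram_result")
}

# Write bipartition supports into the internal node labels of a tree.
label_supports <- function(tree, support) {
  labs <- tree$tip.label
  nt <- length(labs)
  anchor <- labs[order(labs)][1L]
  sets <- edge_tip_sets(tree)
  node_lab <- rep("", tree$Nnode)
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (length(s) <= 1L || length(s) >= nt - 1L) next
    side <- labs[s]
    if (anchor %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      node_lab[tree$edge[k, 2L] - nt] <- format(support[[key]], digits = 3)
  }
  tree$node.label <- node_lab
  tree
}

#' @export
print.phylogram_result <- function(x, ...) {
  cat("Expression phylogram (", length(x$tree$tip.label), " taxa, B = ",
      x$B, " gene bootstraps)\n", sep = "")
  cat("internal-edge supports:\n")
  print(round(x$support, 3))
  invisible(x)
}
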