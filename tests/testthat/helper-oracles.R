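# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from the definitions, not by calling the
# package code paths they verify.

# Doubly-trimmed weighted mean of M-values, straight from the definition:
# log-ratios M and absolute log-intensities A against a reference library,
# trim both tails of each, precision weights by the delta method, factors
# rescaled to unit geometric mean.
tmm_oracle <- function(counts, lib = colSums(counts),
                       trim_m = 0.3, trim_a = 0.05, ref = NULL) {
  if (is.null(ref)) {
    uq <- apply(counts, 2, stats::quantile, 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- sapply(seq_len(ncol(counts)), function(j) {
    o <- counts[, j]; r <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  })
  f / exp(mean(log(f)))
}

# GLS by explicit matrix inversion, scale profiled by ML.
gls_oracle <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
  list(beta = drop(beta), sigma2_ml = s2, loglik = ll)
}

# Spearman correlation as rank-then-Pearson (average ranks for ties).
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Exact OU transition simulation along the branches of a tree: child value
# = parent * e^(-a t) + theta (1 - e^(-a t)) + Gaussian innovation with the
# exact transition variance; the root is drawn from the stationary
# distribution. An independent check of the stationary covariance matrix.
simulate_ou_recursive <- function(tree, alpha, sigma2, theta = 0,
                                  n_rep = 1) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  pre <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  out <- matrix(NA_real_, n_rep, nt, dimnames = list(NULL, tree$tip.label))
  svar <- sigma2 / (2 * alpha)
  for (r in seq_len(n_rep)) {
    val <- numeric(nn)
    val[root] <- theta + stats::rnorm(1, 0, sqrt(svar))
    for (k in pre) {
      par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
      t <- tree$edge.length[k]
      m <- val[par] * exp(-alpha * t) + theta * (1 - exp(-alpha * t))
      v <- svar * (1 - exp(-2 * alpha * t))
      val[chi] <- stats::rnorm(1, m, sqrt(v))
    }
    out[r, ] <- val[seq_len(nt)]
  }
  out
}

# Brownian motion simulated branch by branch (root at 0).
simulate_bm_recursive <- function(tree, sigma2, n_rep = 1) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  pre <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  out <- matrix(NA_real_, n_rep, nt, dimnames = list(NULL, tree$tip.label))
  for (r in seq_len(n_rep)) {
    val <- numeric(nn)
    for (k in pre) {
      par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
      val[chi] <- val[par] +
        stats::rnorm(1, 0, sqrt(sigma2 * tree$edge.length[k]))
    }
    out[r, ] <- val[seq_len(nt)]
  }
  out
}

# One BM draw at the tips as a named vector (chol of the shared-path
# matrix); convenience for signal/regression tests.
bm_tip_draw <- function(tree, sigma2 = 1) {
  V <- sigma2 * longsig::shared_path_matrix(tree)
  y <- drop(t(chol(V)) %*% stats::rnorm(nrow(V)))
  stats::setNames(y, tree$tip.label)
}

# Random count fixture without all-zero rows, for TMM property tests.
random_count_fixture <- function(n_genes = 10, n_sp = 6) {
  cnt <- matrix(stats::rnbinom(n_genes * n_sp,
                               mu = 200 * exp(stats::rnorm(n_genes)),
                               size = 5),
                n_genes, n_sp,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_sp))))
  cnt[cnt == 0] <- 1
  cnt
}
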