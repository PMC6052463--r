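#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood estimate of Pagel's lambda for a tip trait: the
#' multiplier on the off-diagonal Brownian-motion covariance, estimated by
#' maximizing the intercept-only GLS likelihood over \eqn{\lambda \in [0,1]}
#' with the scale profiled. Lambda near 1 indicates BM-like phylogenetic
#' signal, near 0 indicates tip values that ignore the tree.
#'
#' @param y named numeric vector of tip values (names matched to tip
#'   labels; unnamed vectors are assumed tree-ordered).
#' @param tree a rooted `phylo` object with >= 4 tips.
#' @return list with `lambda`, `loglik`, and `flat` (TRUE when the profile
#'   likelihood is numerically flat over `[0, 1]`, in which case the
#'   estimate is arbitrary within the interval).
#' @export
pagels_lambda <- function(y, tree) {
  y <- align_to_tips(y, tree)
  n <- length(y)
  if (n < 4) stop("need at least 4 taxa", call. = FALSE)
  Vbm <- shared_path_matrix(tree)
  dV <- diag(Vbm)
  fam <- function(lam) {
    V <- Vbm * lam
    diag(V) <- dV
    V
  }
  X <- matrix(1, n, 1)
  ll <- function(lam) gls_profile_loglik(y, X, fam, lam)
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  # the interior optimum can miss a boundary maximum
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2]), ]
  grid <- vapply(seq(0, 1, length.out = 11), ll, numeric(1))
  flat <- (max(grid) - min(grid)) < 1e-8
  list(lambda = unname(best[1]), loglik = unname(best[2]), flat = flat)
}

#' Blomberg's K phylogenetic signal
#'
#' Ratio of the observed mean squared deviation from the phylogenetically
#' estimated mean (ordinary vs phylogenetically weighted) to its Brownian-
#' motion expectation:
#' \deqn{K = \frac{MSE_0 / MSE}{(\mathrm{tr}(V) - n / (1'V^{-1}1)) / (n-1)}}
#' with `V` the BM covariance structure. K = 1 is the BM expectation; K is
#' invariant to affine transformations of `y`.
#'
#' @inheritParams pagels_lambda
#' @return numeric scalar K (> 0).
#' @export
blombergs_K <- function(y, tree) {
  y <- align_to_tips(y, tree)
  n <- length(y)
  if (n < 4) stop("need at least 4 taxa", call. = FALSE)
  V <- shared_path_matrix(tree)
  Vi <- solve(V)
  one <- rep(1, n)
  denom1 <- drop(one %*% Vi %*% one)
  ahat <- drop(one %*% Vi %*% y) / denom1
  r <- y - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(r %*% Vi %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

# Align a (possibly named) tip-value vector to tree$tip.label order.
align_to_tips <- function(y, tree) {
  labs <- tree$tip.label
  if (!is.null(names(y))) {
    missing <- setdiff(labs, names(y))
    if (length(missing))
      stop("tip values missing for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    y <- y[labs]
  } else if (length(y) != length(labs)) {
    stop("length of 'y' does not match the number of tips", call. = FALSE)
  }
  as.numeric(y)
}
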