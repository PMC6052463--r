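#' Evolutionary covariance models
#'
#' Residual-covariance structures for trait (or expression) values observed
#' at the tips of a phylogeny. Four kinds are supported:
#'
#' * `null` -- no phylogenetic structure, \eqn{V = \sigma^2 I};
#' * `bm` -- Brownian motion, \eqn{V_{ij} = \sigma^2 t_{ij}} with
#'   \eqn{t_{ij}} the shared root-to-MRCA path length;
#' * `lambda` -- Pagel's lambda transform of BM: off-diagonal entries of the
#'   BM matrix multiplied by \eqn{\lambda \in [0, 1]}, diagonal unchanged;
#' * `ou` -- stationary Ornstein-Uhlenbeck,
#'   \eqn{V_{ij} = \sigma^2/(2\alpha) e^{-\alpha d_{ij}}} with
#'   \eqn{d_{ij}} the patristic distance.
#'
#' @param kind one of `"null"`, `"bm"`, `"lambda"`, `"ou"`.
#' @param sigma2 drift variance per My (> 0).
#' @param lambda Pagel's lambda in `[0, 1]` (lambda kind only).
#' @param alpha OU selection strength per My (> 0; ou kind only).
#' @return an object of class `cov_model`.
#' @export
cov_model <- function(kind = c("null", "bm", "lambda", "ou"),
                      sigma2 = 1, lambda = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be a positive number", call. = FALSE)
  if (kind == "lambda") {
    if (is.null(lambda) || lambda < 0 || lambda > 1)
      stop("lambda kind requires 'lambda' in [0, 1]", call. = FALSE)
  }
  if (kind == "ou") {
    if (is.null(alpha) || alpha <= 0)
      stop("ou kind requires 'alpha' > 0", call. = FALSE)
  }
  structure(list(kind = kind, sigma2 = sigma2, lambda = lambda, alpha = alpha),
            class = "cov_model")
}

#' @export
print.cov_model <- function(x, ...) {
  cat("Evolutionary covariance model:", x$kind, "\n")
  cat("  sigma2 =", x$sigma2)
  if (!is.null(x$lambda)) cat(", lambda =", x$lambda)
  if (!is.null(x$alpha)) cat(", alpha =", x$alpha)
  cat("\n")
  invisible(x)
}

#' Species covariance matrix under an evolutionary model
#'
#' Builds the species-by-species residual covariance implied by a
#' [cov_model()] on a rooted time-calibrated tree. Non-positive-definite
#' results (e.g. from zero-length branches creating tied rows) are repaired
#' by adding a small diagonal jitter, with a warning.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param model a [cov_model()].
#' @param jitter relative diagonal jitter used when the matrix fails a
#'   Cholesky factorization.
#' @return symmetric positive-definite matrix with tip labels as dimnames.
#' @export
covariance_matrix <- function(tree, model, jitter = 1e-8) {
  stopifnot(inherits(model, "cov_model"))
  n <- length(tree$tip.label)
  V <- switch(model$kind,
    null = {
      M <- diag(model$sigma2, n)
      dimnames(M) <- list(tree$tip.label, tree$tip.label)
      M
    },
    bm = model$sigma2 * shared_path_matrix(tree),
    lambda = {
      M <- model$sigma2 * shared_path_matrix(tree)
      d <- diag(M)
      M <- M * model$lambda
      diag(M) <- d
      M
    },
    ou = {
      D <- patristic_matrix(tree)
      model$sigma2 / (2 * model$alpha) * exp(-model$alpha * D)
    })
  V <- (V + t(V)) / 2
  ok <- !inherits(try(chol(V), silent = TRUE), "try-error")
  if (!ok) {
    warning("covariance matrix not positive definite; adding diagonal jitter")
    V <- V + diag(jitter * mean(diag(V)), n)
  }
  V
}
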