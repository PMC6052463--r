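#' Generalized least squares with a fixed correlation structure
#'
#' Fits `y ~ X` under the model \eqn{y \sim N(X\beta, \sigma^2 V)} where `V`
#' is a known (up to the profiled scale \eqn{\sigma^2}) species covariance
#' structure. The scale is profiled by maximum likelihood
#' (\eqn{\hat\sigma^2 = r'V^{-1}r / n}); standard errors and slope t-tests
#' use the unbiased residual variance with `n - p` degrees of freedom, the
#' usual GLS convention.
#'
#' @param y numeric response vector (one value per species).
#' @param X design matrix (rows aligned with `y`). A plain vector is treated
#'   as a single column; no intercept is added implicitly.
#' @param V positive-definite covariance structure, rows/cols aligned to `y`.
#' @return list with elements `coefficients`, `se`, `t`, `p` (two-sided,
#'   t with n - p df), `sigma2_ml`, `sigma2` (unbiased), `loglik` (profiled
#'   ML log-likelihood), `df_residual`, `fitted`, `residuals`, `n`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  L <- try(chol(V), silent = TRUE)
  if (inherits(L, "try-error"))
    stop("'V' must be positive definite", call. = FALSE)
  # whiten: solve L' z = . (V = L'L with R's upper-triangular chol)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-14)
    stop("singular design matrix", call. = FALSE)
  beta <- solve(XtX, crossprod(Xw, yw))
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  p <- ncol(X)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  df <- n - p
  sigma2 <- if (df > 0) rss / df else NA_real_
  covb <- solve(XtX) * sigma2
  se <- sqrt(diag(covb))
  tval <- drop(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df)
  fitted <- drop(X %*% beta)
  list(coefficients = drop(beta), se = se, t = tval, p = pval,
       sigma2_ml = sigma2_ml, sigma2 = sigma2, loglik = loglik,
       df_residual = df, fitted = fitted, residuals = y - fitted, n = n)
}

# Profiled log-likelihood of an intercept+slope (or arbitrary-design) GLS
# under a parametric correlation family. Used by the lambda/OU optimizers.
# family: function(par) -> V matrix
gls_profile_loglik <- function(y, X, family, par) {
  V <- family(par)
  fit <- try(gls_fit(y, X, V), silent = TRUE)
  if (inherits(fit, "try-error")) return(-Inf)
  fit$loglik
}
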