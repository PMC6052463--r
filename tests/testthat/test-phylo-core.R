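star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, n)
  tr
}

test_that("covariance builders honor the model endpoint identities", {
  tr <- star_tree(6, depth = 3)
  Vbm <- covariance_matrix(tr, cov_model("bm", sigma2 = 1))
  expect_equal(unname(Vbm), diag(3, 6), tolerance = 1e-12)
  fix <- drosophila_tree()
  Vb <- covariance_matrix(fix, cov_model("bm", sigma2 = 0.7))
  V1 <- covariance_matrix(fix, cov_model("lambda", sigma2 = 0.7,
                                         lambda = 1))
  V0 <- covariance_matrix(fix, cov_model("lambda", sigma2 = 0.7,
                                         lambda = 0))
  expect_equal(V1, Vb, tolerance = 1e-12)
  expect_equal(unname(V0), diag(diag(Vb)), tolerance = 1e-12)
  Vou <- covariance_matrix(fix, cov_model("ou", sigma2 = 0.4,
                                          alpha = 0.08))
  expect_equal(unname(diag(Vou)), rep(0.4 / 0.16, 14), tolerance = 1e-12)
  expect_true(isSymmetric(Vou))
  expect_true(all(eigen(Vou, only.values = TRUE)$values > 0))
})

test_that("GLS reduces to OLS under identity covariance and matches the matrix oracle", {
  set.seed(31)
  n <- 10
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  f <- gls_fit(y, X, diag(n))
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(f$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-10)
  # exact fit
  f0 <- gls_fit(drop(X %*% c(3, -1)), X, diag(n))
  expect_equal(unname(f0$coefficients), c(3, -1), tolerance = 1e-10)
  expect_lt(sum(f0$residuals^2), 1e-18)
  # 5-taxon fixture with a hand-built V vs brute-force linear algebra
  set.seed(32)
  A <- matrix(rnorm(25), 5)
  V <- crossprod(A) + diag(5)
  y5 <- rnorm(5); X5 <- cbind(1, rnorm(5))
  f5 <- gls_fit(y5, X5, V)
  o5 <- gls_oracle(y5, X5, V)
  expect_equal(unname(f5$coefficients), o5$beta, tolerance = 1e-10)
  expect_equal(f5$sigma2_ml, o5$sigma2_ml, tolerance = 1e-10)
  expect_equal(f5$loglik, o5$loglik, tolerance = 1e-8)
  expect_error(gls_fit(y5, cbind(rep(1, 5), rep(1, 5)), V), "singular")
})

test_that("GLS log-likelihood is invariant to taxon reordering", {
  set.seed(33)
  tr <- drosophila_tree()
  V <- covariance_matrix(tr, cov_model("bm"))
  y <- bm_tip_draw(tr)
  x <- rnorm(14); names(x) <- tr$tip.label
  f <- gls_fit(y, cbind(1, x), V)
  perm <- sample(14)
  f2 <- gls_fit(y[perm], cbind(1, x[perm]),
                V[names(y)[perm], names(y)[perm]])
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("lambda-model likelihood nests BM at 1 and independence at 0", {
  set.seed(34)
  tr <- drosophila_tree()
  Vbm <- shared_path_matrix(tr)
  for (rep in 1:5) {
    y <- bm_tip_draw(tr)
    X <- matrix(1, 14, 1)
    lam1 <- Vbm
    ll_lam1 <- gls_fit(y, X, lam1)$loglik
    expect_equal(ll_lam1, gls_fit(y, X, Vbm)$loglik, tolerance = 1e-8)
    lam0 <- Vbm * 0; diag(lam0) <- diag(Vbm)
    # ultrametric: diag is constant, so lambda = 0 equals the null model
    expect_equal(gls_fit(y, X, lam0)$loglik,
                 gls_fit(y, X, diag(14))$loglik, tolerance = 1e-8)
  }
})

test_that("Pagel's lambda recovers high signal under BM and low under noise", {
  set.seed(35)
  tr <- drosophila_tree()
  lam_bm <- replicate(200, pagels_lambda(bm_tip_draw(tr), tr)$lambda)
  expect_gt(median(lam_bm), 0.9)
  lam_iid <- replicate(200, {
    pagels_lambda(stats::setNames(rnorm(14), tr$tip.label), tr)$lambda
  })
  expect_lt(median(lam_iid), 0.1)
  # affine invariance
  y <- bm_tip_draw(tr)
  expect_equal(pagels_lambda(3 * y + 7, tr)$lambda,
               pagels_lambda(y, tr)$lambda, tolerance = 1e-6)
})

test_that("lambda and K agree with an established independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(36)
  tr <- drosophila_tree()
  for (rep in 1:3) {
    y <- bm_tip_draw(tr)
    ours <- pagels_lambda(y, tr)
    ref <- phytools::phylosig(tr, y, method = "lambda")
    expect_equal(ours$lambda, ref$lambda, tolerance = 1e-4)
    expect_equal(blombergs_K(y, tr),
                 as.numeric(phytools::phylosig(tr, y, method = "K")),
                 tolerance = 1e-8)
  }
})

test_that("Blomberg's K is exactly 1 on star trees, scale invariant, and BM-calibrated", {
  set.seed(37)
  tr <- star_tree(8, depth = 2)
  for (rep in 1:5) {
    y <- stats::setNames(rnorm(8), tr$tip.label)
    expect_equal(blombergs_K(y, tr), 1, tolerance = 1e-10)
  }
  fix <- drosophila_tree()
  y <- bm_tip_draw(fix)
  expect_equal(blombergs_K(5 * y, fix), blombergs_K(y, fix),
               tolerance = 1e-10)
  ks <- replicate(500, blombergs_K(bm_tip_draw(fix), fix))
  expect_equal(mean(ks), 1, tolerance = 0.1)
})

test_that("regime painting covers every branch and weights sum to one", {
  tr <- drosophila_tree()
  reg <- drosophila_regimes()
  for (groups in reg[c("k2", "k3")]) {
    p <- paint_regimes(tr, groups)
    expect_false(anyNA(p$edge_regime))
    expect_equal(length(p$edge_regime), nrow(tr$edge))
    for (a in c(0.01, 0.2, 3)) {
      W <- ou_weight_matrix(tr, p, a)
      expect_equal(unname(rowSums(W)), rep(1, 14), tolerance = 1e-12)
      expect_true(all(W >= 0))
    }
  }
  # subgenus split: every melanogaster-group terminal branch is Sophophora
  p2 <- paint_regimes(tr, reg$k2)
  tips <- tr$edge[, 2] <= 14
  tip_regime <- p2$edge_regime[tips][order(tr$edge[tips, 2])]
  expect_identical(tip_regime, unname(reg$k2[tr$tip.label]))
})

test_that("multi-optimum OU fit nests BM and is monotone in regime count", {
  set.seed(38)
  tr <- drosophila_tree()
  reg <- drosophila_regimes()
  for (rep in 1:3) {
    y <- bm_tip_draw(tr)
    f1 <- hansen_fit_and_lrt(y, tr, groups = NULL)
    f2 <- hansen_fit_and_lrt(y, tr, groups = reg$k2)
    f3 <- hansen_fit_and_lrt(y, tr, groups = reg$k3)
    # OU likelihood never falls below BM (boundary fallback handles alpha -> 0)
    expect_gte(f1$loglik_ou, f1$loglik_bm - 1e-6)
    # nested regime maps: likelihood non-decreasing in k
    expect_gte(f2$loglik_ou, f1$loglik_ou - 1e-4)
    expect_gte(f3$loglik_ou, f2$loglik_ou - 1e-4)
    expect_true(all(c(f1$p, f2$p, f3$p) >= 0 &
                    c(f1$p, f2$p, f3$p) <= 1))
  }
})

test_that("strong two-regime OU data is classified as OU for most genes", {
  set.seed(39)
  tr <- drosophila_tree()
  reg <- drosophila_regimes()
  painting <- paint_regimes(tr, reg$k2)
  alpha <- 0.3; sigma2 <- 1
  theta <- c(Drosophila = 2, Sophophora = -2)
  V <- covariance_matrix(tr, cov_model("ou", sigma2 = sigma2,
                                       alpha = alpha))
  L <- t(chol(V))
  W <- ou_weight_matrix(tr, painting, alpha)
  n_genes <- 200
  hits <- 0
  for (i in seq_len(n_genes)) {
    y <- drop(W %*% theta[painting$regimes] + L %*% rnorm(14))
    names(y) <- tr$tip.label
    f <- hansen_fit_and_lrt(y, tr, groups = reg$k2)
    if (f$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_genes, 0.85)
})
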