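test_that("generated trees are ultrametric at the requested depth and reproducible", {
  tr <- generate_tree(14, 56, seed = 3)
  depths <- ape::node.depth.edgelength(tr)[seq_len(14)]
  expect_equal(depths, rep(56, 14), tolerance = 1e-10)
  expect_true(ape::is.ultrametric(tr))
  expect_identical(ape::write.tree(generate_tree(14, 56, seed = 3)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(generate_tree(14, 56, seed = 4)),
                         ape::write.tree(tr)))
  expect_error(generate_tree(2, 56), "n_taxa")
})

test_that("packaged fixture tree has the expected group structure", {
  tr <- drosophila_tree()
  expect_equal(length(tr$tip.label), 14)
  expect_true(ape::is.ultrametric(tr))
  expect_equal(tree_depth(tr), 56)
  g <- drosophila_groups()
  mel <- g$species[g$species_group == "melanogaster"]
  soph <- g$species[g$subgenus == "Sophophora"]
  expect_equal(length(mel), 9)
  # the melanogaster group is monophyletic and nested inside Sophophora
  mel_mrca <- ape::getMRCA(tr, mel)
  mel_clade <- ape::extract.clade(tr, mel_mrca)$tip.label
  expect_setequal(mel_clade, mel)
  soph_clade <- ape::extract.clade(tr, ape::getMRCA(tr, soph))$tip.label
  expect_setequal(soph_clade, soph)
  expect_true(all(mel %in% soph_clade))
})

test_that("trait generator matches the stationary OU variance and is seed-stable", {
  tr <- drosophila_tree()
  cfg <- sim_config(alpha_sim = 0.1, sigma2_sim = 0.3)
  t1 <- generate_traits(tr, cfg, seed = 5)
  t2 <- generate_traits(tr, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$lifespan_days > 0))
  # Monte-Carlo marginal variance of log lifespan vs sigma2 / (2 alpha)
  draws <- replicate(400, {
    log(generate_traits(tr, cfg, seed = sample.int(1e6, 1))$lifespan_days[1])
  })
  expect_equal(stats::var(draws), 0.3 / (2 * 0.1), tolerance = 0.2)
  # degenerate drift: all species sit at the optimum
  cfg0 <- sim_config(alpha_sim = 0.1, sigma2_sim = 1e-12)
  t0 <- generate_traits(tr, cfg0, seed = 1)
  expect_equal(t0$lifespan_days, rep(25, 14), tolerance = 1e-3)
})

test_that("OU tip draws match the recursive branch-by-branch oracle", {
  set.seed(71)
  tr <- ape::rcoal(5)
  tr$edge.length <- tr$edge.length / tree_depth(tr) * 10
  alpha <- 0.15; sigma2 <- 0.6
  V <- covariance_matrix(tr, cov_model("ou", sigma2 = sigma2,
                                       alpha = alpha))
  sims <- simulate_ou_recursive(tr, alpha, sigma2, theta = 0, n_rep = 2000)
  S <- stats::cov(sims)[rownames(V), colnames(V)]
  expect_lt(max(abs(S - V)) / max(abs(V)), 0.1)
  # and the BM builder against its own recursive oracle
  Vbm <- covariance_matrix(tr, cov_model("bm", sigma2 = sigma2))
  simb <- simulate_bm_recursive(tr, sigma2, n_rep = 2000)
  Sb <- stats::cov(simb)[rownames(Vbm), colnames(Vbm)]
  expect_lt(max(abs(Sb - Vbm)) / max(abs(Vbm)), 0.1)
})

test_that("expression generator plants the requested signature", {
  tr <- drosophila_tree()
  cfg <- sim_config(n_genes = 500, signature_fraction = 0.1,
                    effect_size = 0.9)
  traits <- generate_traits(tr, cfg, seed = 2)
  ex <- generate_expression(tr, traits, cfg, seed = 2)
  std <- ex$standardized
  expect_equal(expr_stage(std), "standardized")
  expect_equal(unname(rowMeans(std)), rep(0, 500), tolerance = 1e-12)
  expect_equal(unname(apply(std, 1, sd)), rep(1, 500), tolerance = 1e-12)
  expect_equal(table(ex$truth$label != "null")[["TRUE"]], 50)
  expect_true(all(ex$truth$beta_true[ex$truth$label == "null"] == 0))
  z <- standardize_trait(setNames(traits$lifespan_days, traits$species))
  sig <- ex$truth$label != "null"
  r2 <- apply(std[sig, , drop = FALSE], 1,
              function(g) cor(g, z[colnames(std)])^2)
  expect_equal(mean(r2), 0.9, tolerance = 0.02)
  # sign of the planted slope matches the label
  slopes <- apply(std[sig, ], 1, function(g) cor(g, z[colnames(std)]))
  expect_true(all(sign(slopes) ==
                  sign(ex$truth$beta_true[sig])))
  # determinism
  ex2 <- generate_expression(tr, traits, cfg, seed = 2)
  expect_identical(ex$standardized, ex2$standardized)
})

test_that("zero effect size makes signature genes indistinguishable from null", {
  tr <- drosophila_tree()
  cfg <- sim_config(n_genes = 300, signature_fraction = 0.2,
                    effect_size = 0)
  traits <- generate_traits(tr, cfg, seed = 8)
  ex <- generate_expression(tr, traits, cfg, seed = 8)
  z <- standardize_trait(setNames(traits$lifespan_days, traits$species))
  sig <- ex$truth$label != "null"
  slopes <- apply(as.matrix(ex$standardized)[sig, ], 1,
                  function(g) cor(g, z[colnames(ex$standardized)]))
  expect_lt(abs(mean(slopes)), 0.15)
})

test_that("count generator inverts the RPKM transform", {
  lr <- matrix(log(10), 1, 3,
               dimnames = list("g1", c("s1", "s2", "s3")))
  cm <- expression_to_counts(lr, lengths = 1000, library_sizes = 1e6,
                             seed = 1)
  # expected count is 10; Poisson draws stay near it
  expect_true(all(cm$counts >= 0))
  reps <- replicate(300, {
    mean(expression_to_counts(lr, 1000, 1e6,
                              seed = sample.int(1e6, 1))$counts)
  })
  expect_equal(mean(reps), 10, tolerance = 0.2)
  # zero expression gives zero counts with certainty
  lr0 <- matrix(-Inf, 1, 3, dimnames = dimnames(lr))
  expect_true(all(expression_to_counts(lr0, 1000, 1e6, seed = 1)$counts == 0))
  expect_error(expression_to_counts(lr, -5, 1e6), "positive")
  # large libraries: log-RPKM round trip recovers the generating values
  set.seed(9)
  lrg <- matrix(rnorm(60, 2, 1), 20, 3,
                dimnames = list(paste0("g", 1:20), c("s1", "s2", "s3")))
  cm2 <- expression_to_counts(lrg, lengths = rep(1500, 20),
                              library_sizes = 1e9, seed = 2)
  back <- to_log_rpkm(count_matrix(cm2$counts, rep(1500, 20),
                                   rep(1e9, 3)))
  expect_equal(unname(as.matrix(back)), unname(lrg), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("DE table generator honors the agreement probability", {
  tr <- drosophila_tree()
  cfg <- sim_config(n_genes = 400, signature_fraction = 0.75,
                    effect_size = 0.5)
  traits <- generate_traits(tr, cfg, seed = 4)
  ex <- generate_expression(tr, traits, cfg, seed = 4)
  de1 <- generate_de_table(ex$truth, q = 1, n = 100, seed = 1)
  sig <- setNames(sign(ex$truth$beta_true), ex$truth$gene)
  sig <- sig[sig != 0]
  m <- match_directions(sig, de1)
  expect_equal(m$k_same, 100)
  expect_equal(m$k_opp, 0)
  # q = 0.5: mean same-direction count over replicates ~ n/2
  same <- replicate(200, {
    de <- generate_de_table(ex$truth, q = 0.5, n = 200,
                            seed = sample.int(1e6, 1))
    match_directions(sig, de)$k_same
  })
  expect_equal(mean(same), 100, tolerance = 0.03)
  expect_identical(generate_de_table(ex$truth, 0.6, 50, seed = 7),
                   generate_de_table(ex$truth, 0.6, 50, seed = 7))
  expect_error(generate_de_table(ex$truth, 0.5, 1e5), "exceeds")
})
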