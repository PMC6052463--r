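make_cm <- function(counts, len = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_matrix(counts, len %||% rep(1000, nrow(counts)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("low-expression filter implements the <3-counts-in-3-species rule", {
  cnt <- rbind(a = c(0, 0, 0, 9, 9),    # 3 species below 3 -> removed
               b = c(3, 3, 3, 0, 0),    # only 2 below -> retained
               c = c(2, 2, 9, 9, 9),    # 2 below -> retained
               d = c(0, 1, 2, 9, 9),    # 3 below -> removed
               e = c(5, 5, 5, 5, 5))
  m <- filter_low_expression(make_cm(cnt))
  expect_identical(rownames(m$counts), c("b", "c", "e"))
  # all genes clear the threshold -> identity
  all_hi <- make_cm(matrix(5, 4, 5))
  expect_identical(filter_low_expression(all_hi)$counts, all_hi$counts)
  expect_warning(filter_low_expression(make_cm(matrix(1L, 2, 5))),
                 "all genes")
})

test_that("TMM factors are unit for identical or rescaled libraries", {
  cnt <- random_count_fixture(50, 2)
  m <- make_cm(cbind(s1 = cnt[, 1], s2 = cnt[, 1]))
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)
  # pure depth change, composition unchanged
  m2 <- make_cm(cbind(s1 = cnt[, 1], s2 = 4L * cnt[, 1]))
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
  degen <- count_matrix(cbind(s1 = c(1, 2), s2 = c(0, 0)),
                        gene_length = c(1000, 1000), lib_size = c(3, 10))
  expect_error(tmm_factors(degen), "all-zero")
})

test_that("TMM factors equal the brute-force trimmed weighted mean oracle", {
  set.seed(101)
  for (rep in 1:8) {
    cnt <- random_count_fixture(n_genes = 10, n_sp = sample(3:8, 1))
    m <- make_cm(cnt)
    expect_equal(unname(tmm_factors(m)), unname(tmm_oracle(cnt)),
                 tolerance = 1e-9)
  }
  # 6-gene worked example
  cnt6 <- matrix(c(100, 200, 300,  50, 400,  80,
                   110, 180, 290, 500, 420,  90,
                   ## deliberately skewed third library
                   400, 150, 900,  60, 300,  70), 6, 3,
                 dimnames = list(paste0("g", 1:6), c("s1", "s2", "s3")))
  m6 <- make_cm(cnt6)
  expect_equal(unname(tmm_factors(m6)), unname(tmm_oracle(cnt6)),
               tolerance = 1e-9)
})

test_that("log-RPKM conversion does the unit arithmetic and is scale invariant", {
  m <- count_matrix(matrix(10, 1, 2, dimnames = list("g1", c("a", "b"))),
                    gene_length = 1000, lib_size = c(1e6, 1e6))
  e <- to_log_rpkm(m)
  expect_equal(unname(as.matrix(e))[1, ], rep(log(10), 2),
               tolerance = 1e-12)
  expect_equal(expr_stage(e), "log_rpkm")
  # zero counts: -Inf without pseudocount, finite with one
  m0 <- count_matrix(matrix(c(0, 5), 1, 2,
                            dimnames = list("g1", c("a", "b"))),
                     gene_length = 1000, lib_size = c(1e6, 1e6))
  expect_true(is.infinite(as.matrix(to_log_rpkm(m0))[1, 1]))
  expect_true(all(is.finite(as.matrix(to_log_rpkm(m0,
                                                  pseudocount = 1e-6)))))
  # doubling counts and library sizes leaves values unchanged
  cnt <- random_count_fixture(20, 4)
  m1 <- make_cm(cnt)
  m2 <- count_matrix(2 * cnt, m1$gene_length, 2 * m1$lib_size)
  expect_equal(as.matrix(to_log_rpkm(m1)), as.matrix(to_log_rpkm(m2)),
               tolerance = 1e-12)
})

test_that("standardization yields exact row moments and is idempotent", {
  set.seed(11)
  v <- matrix(rnorm(1400), 100, 14,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:14)))
  z <- standardize(expr_matrix(v, "log_rpkm"))
  expect_equal(unname(rowMeans(z)), rep(0, 100), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 100), tolerance = 1e-12)
  expect_equal(as.matrix(standardize(z)), as.matrix(z), tolerance = 1e-12)
  expect_equal(unname(as.matrix(standardize(rbind(g1 = c(1, 2, 3))))),
               matrix(c(-1, 0, 1), 1), ignore_attr = TRUE)
  expect_warning(z2 <- standardize(rbind(g1 = c(1, 2, 3),
                                         g2 = c(5, 5, 5))),
                 "dropped")
  expect_equal(nrow(z2), 1)
})

test_that("normality QC fraction is calibrated on Gaussian rows and drops for heavy tails", {
  set.seed(21)
  gauss <- matrix(rnorm(14 * 1000), 1000, 14)
  frac <- normalcy_fraction(gauss, alpha = 0.05)
  expect_equal(frac, 0.95, tolerance = 0.03)
  heavy <- matrix(rcauchy(14 * 500), 500, 14)
  expect_lt(normalcy_fraction(heavy), frac - 0.2)
  one <- matrix(rnorm(14), 1, 14)
  p <- stats::shapiro.test(one[1, ])$p.value
  expect_equal(normalcy_fraction(one), as.numeric(p >= 0.05))
})

test_that("pipeline on synthetic counts recovers the generating expression", {
  study <- simulate_study(sim_config(n_genes = 300, library_sizes = 1e7,
                                     seed = 3))
  norm <- normalize_counts(study$counts)
  std <- norm$standardized
  gen <- as.matrix(study$expression$standardized)[rownames(std),
                                                  colnames(std)]
  cors <- vapply(seq_len(nrow(std)),
                 function(i) cor(std[i, ], gen[i, ]), numeric(1))
  expect_gt(median(cors), 0.95)
  # deeper libraries recover better
  study2 <- simulate_study(sim_config(n_genes = 300, library_sizes = 1e8,
                                      seed = 3))
  norm2 <- normalize_counts(study2$counts)
  std2 <- norm2$standardized
  gen2 <- as.matrix(study2$expression$standardized)[rownames(std2),
                                                    colnames(std2)]
  cors2 <- vapply(seq_len(nrow(std2)),
                  function(i) cor(std2[i, ], gen2[i, ]), numeric(1))
  expect_gt(median(cors2), median(cors))
})
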