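#' Standardize a life-history trait
#'
#' Log-transforms a positive trait and standardizes it to mean 0, sample
#' SD 1 across species.
#'
#' @param x positive numeric vector (e.g. median lifespan in days).
#' @return numeric vector, mean 0 and SD 1, same names as `x`.
#' @export
standardize_trait <- function(x) {
  if (any(x <= 0)) stop("trait values must be positive", call. = FALSE)
  z <- log(x)
  z <- (z - mean(z)) / stats::sd(z)
  names(z) <- names(x)
  z
}

#' Phylogenetic regression of one gene under four residual models
#'
#' Regresses a gene's standardized expression (response) on a standardized
#' log trait (single predictor plus intercept) by generalized least
#' squares under four residual-covariance models: Null (independent
#' species), Brownian motion, BM transformed by Pagel's lambda, and
#' stationary Ornstein-Uhlenbeck. For Lambda and OU the structure
#' parameter is estimated jointly with the coefficients by maximum
#' likelihood (bounded search with the coefficients and scale profiled).
#' The best model is the one with the highest log-likelihood, with ties
#' (within 1e-6) broken toward the simpler model; slope p-values are
#' two-sided t-tests with n - 2 degrees of freedom, conditional on the
#' estimated covariance parameters.
#'
#' @param y named numeric vector of standardized expression values.
#' @param trait named numeric vector of standardized trait values.
#' @param tree rooted `phylo` covering the species.
#' @return list of class `gene_regression`: `models` (data.frame with one
#'   row per model: `model`, `loglik`, `slope`, `se`, `t`, `p`,
#'   `parameter`), `best` (model name), `slope`, `p`, `sign`, `lambda`,
#'   `alpha`.
#' @export
fit_gene_all_models <- function(y, trait, tree) {
  y <- align_to_tips(y, tree)
  trait <- align_to_tips(trait, tree)
  n <- length(y)
  X <- cbind(intercept = 1, trait = trait)
  Vbm <- shared_path_matrix(tree)
  D <- patristic_matrix(tree)[tree$tip.label, tree$tip.label]
  T <- tree_depth(tree)

  fits <- list()
  fits$null <- c(gls_fit(y, X, diag(n)), parameter = NA_real_)
  fits$bm <- c(gls_fit(y, X, Vbm), parameter = NA_real_)

  dV <- diag(Vbm)
  lam_V <- function(lam) { V <- Vbm * lam; diag(V) <- dV; V }
  ll_lam <- function(lam) gls_profile_loglik(y, X, lam_V, lam)
  opt <- stats::optimize(ll_lam, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll_lam(0)),
                c(1, ll_lam(1)))
  lam_hat <- cand[which.max(cand[, 2]), 1]
  fits$lambda <- c(gls_fit(y, X, lam_V(lam_hat)), parameter = lam_hat)

  ou_V <- function(a) exp(-a * D)
  ll_ou <- function(la) gls_profile_loglik(y, X, ou_V, exp(la))
  lo <- log(1e-6); hi <- log(50 / T)
  cuts <- seq(lo, hi, length.out = 4)
  bo <- NULL
  for (s in seq_len(3)) {
    o <- stats::optimize(ll_ou, cuts[s:(s + 1)], maximum = TRUE, tol = 1e-8)
    if (is.null(bo) || o$objective > bo$objective) bo <- o
  }
  alpha_hat <- exp(bo$maximum)
  fits$ou <- c(gls_fit(y, X, ou_V(alpha_hat)), parameter = alpha_hat)

  models <- data.frame(
    model = names(fits),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    slope = vapply(fits, function(f) unname(f$coefficients[2]), numeric(1)),
    se = vapply(fits, function(f) unname(f$se[2]), numeric(1)),
    t = vapply(fits, function(f) unname(f$t[2]), numeric(1)),
    p = vapply(fits, function(f) unname(f$p[2]), numeric(1)),
    parameter = vapply(fits, function(f) f$parameter, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  # max likelihood; ties toward the simpler model (listed order)
  best_i <- which(models$loglik > max(models$loglik) - 1e-6)[1]
  structure(list(models = models, best = models$model[best_i],
                 slope = models$slope[best_i], p = models$p[best_i],
                 sign = sign(models$slope[best_i]),
                 lambda = lam_hat, alpha = alpha_hat),
            class = "gene_regression")
}

#' Longevity signature by per-gene phylogenetic regression
#'
#' Applies [fit_gene_all_models()] to every gene of a standardized
#' expression matrix against a standardized log-transformed trait, ranks
#' genes by the best-model slope p-value, and controls the FDR by
#' Benjamini-Hochberg. When `exclude` names species, the regression is
#' additionally rerun without them and the fraction of baseline hits that
#' remain significant is reported (a robustness check against influential
#' species).
#'
#' @param e standardized expression matrix, genes x species.
#' @param traits data.frame with a `species` column and the trait column.
#' @param tree rooted `phylo`.
#' @param trait name of the trait column (default `"lifespan_days"`).
#' @param exclude character vector of species to drop in the robustness
#'   variant (default none).
#' @param p_threshold significance threshold defining the signature hits.
#' @return list of class `signature_result`: `table` (data.frame `gene`,
#'   `best_model`, `slope`, `p`, `q`, `sign`), `n_sig` / `n_sig_01` (hits
#'   at `p_threshold` and 0.01), `p_threshold`, and, when `exclude` is
#'   nonempty, `excluded`, `table_excluded` and `retained_fraction` (share
#'   of baseline hits still significant without the excluded species).
#' @export
run_signature <- function(e, traits, tree, trait = "lifespan_days",
                          exclude = character(), p_threshold = 0.05) {
  v <- as.matrix(e)
  if (!all(c("species", trait) %in% names(traits)))
    stop("traits must have columns 'species' and '", trait, "'",
         call. = FALSE)
  tvec <- stats::setNames(traits[[trait]], traits$species)
  base <- signature_table(v, tvec, tree)
  out <- list(table = base, p_threshold = p_threshold,
              n_sig = sum(base$p < p_threshold),
              n_sig_01 = sum(base$p < 0.01))
  if (length(exclude)) {
    keep <- setdiff(colnames(v), exclude)
    if (length(keep) < 4)
      stop("exclusion leaves fewer than 4 species", call. = FALSE)
    tr2 <- ape::keep.tip(tree, keep)
    tab2 <- signature_table(v[, keep, drop = FALSE], tvec[keep], tr2)
    hits <- base$gene[base$p < p_threshold]
    retained <- if (length(hits))
      mean(tab2$p[match(hits, tab2$gene)] < p_threshold) else NA_real_
    out$excluded <- exclude
    out$table_excluded <- tab2
    out$retained_fraction <- retained
  }
  structure(out, class = "signature_result")
}

signature_table <- function(v, tvec, tree) {
  z <- standardize_trait(tvec[colnames(v)])
  rows <- lapply(seq_len(nrow(v)), function(i) {
    f <- fit_gene_all_models(v[i, ], z, tree)
    gid <- if (is.null(rownames(v))) paste0("g", i) else rownames(v)[i]
    data.frame(gene = gid, best_model = f$best, slope = f$slope, p = f$p,
               sign = f$sign, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab[, c("gene", "best_model", "slope", "p", "q", "sign")]
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Longevity signature:", nrow(x$table), "genes;",
      x$n_sig, "with p <", x$p_threshold, "(", x$n_sig_01, "with p < 0.01)\n")
  if (!is.null(x$retained_fraction))
    cat("retained after excluding", paste(x$excluded, collapse = ", "),
        ":", round(100 * x$retained_fraction), "% of hits\n")
  invisible(x)
}

#' Signature gene signs at a significance threshold
#'
#' Convenience extractor: named vector of correlation signs (+1 / -1) for
#' the genes significant at `p_threshold`, the "top hits" consumed by the
#' concordance tests.
#'
#' @param x a `signature_result`.
#' @param p_threshold threshold (defaults to the one used in the fit).
#' @return named numeric vector of signs.
#' @export
signature_signs <- function(x, p_threshold = NULL) {
  stopifnot(inherits(x, "signature_result"))
  thr <- p_threshold %||% x$p_threshold
  hit <- x$table$p < thr
  stats::setNames(x$table$sign[hit], x$table$gene[hit])
}
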