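#' Ortholog count matrix
#'
#' Container for a gene x species read-count matrix with per-gene transcript
#' lengths and per-species library sizes, the input of the normalization
#' pipeline (filter, TMM, log-RPKM, standardize).
#'
#' @param counts nonnegative integer matrix, genes x species, with unique
#'   row (gene) and column (species) names.
#' @param gene_length positive lengths in bp, one per gene (recycled names
#'   from `counts` when unnamed).
#' @param lib_size per-species library sizes; defaults to column sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_length, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("'counts' needs species column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or species IDs", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and nonnegative", call. = FALSE)
  gene_length <- as.numeric(gene_length)
  if (length(gene_length) != nrow(counts))
    stop("one gene length per gene required", call. = FALSE)
  if (any(gene_length <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  lib_size <- as.numeric(lib_size)
  if (any(lib_size <= 0))
    stop("library sizes must be positive", call. = FALSE)
  structure(list(counts = counts,
                 gene_length = stats::setNames(gene_length, rownames(counts)),
                 lib_size = stats::setNames(lib_size, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "species\n")
  cat("library sizes:", paste(signif(x$lib_size, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Expression matrix with a processing-stage tag
#'
#' A plain numeric matrix (genes x species) carrying a `stage` attribute,
#' either `"log_rpkm"` or `"standardized"`.
#'
#' @param values numeric matrix, genes x species.
#' @param stage processing stage.
#' @return matrix of class `expr_matrix`.
#' @export
expr_matrix <- function(values, stage = c("log_rpkm", "standardized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  structure(values, stage = stage,
            class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param e an `expr_matrix` (or plain matrix, giving `NULL`).
#' @export
expr_stage <- function(e) attr(e, "stage")

#' Remove genes expressed at low levels
#'
#' Drops the ortholog sets with low expression, defined as fewer than
#' `min_count` reads in `min_species` or more species; equivalently, a gene
#' is retained exactly when fewer than `min_species` species fall below
#' `min_count` counts. Applied to raw counts, before any normalization.
#'
#' @param m a [count_matrix()].
#' @param min_count count threshold (default 3).
#' @param min_species number of below-threshold species that triggers
#'   removal (default 3).
#' @return filtered [count_matrix()], gene order preserved.
#' @export
filter_low_expression <- function(m, min_count = 3, min_species = 3) {
  stopifnot(inherits(m, "count_matrix"))
  low <- rowSums(m$counts < min_count)
  keep <- low < min_species
  if (!any(keep)) warning("all genes removed by the low-expression filter")
  out <- m
  out$counts <- m$counts[keep, , drop = FALSE]
  out$gene_length <- m$gene_length[keep]
  out
}

#' Trimmed-mean-of-M-values scale factors
#'
#' Between-library composition correction: for each species a scale factor
#' from the doubly-trimmed weighted mean of the gene-wise log-ratios against
#' a reference library (trim on the log-ratios M and on the absolute
#' log-intensities A), with precision weights from the delta method. Factors
#' are normalized to unit geometric mean. Computed by
#' [edgeR::calcNormFactors()], the reference implementation of the method;
#' by default the reference library is the one whose upper quartile is
#' closest to the mean upper quartile.
#'
#' @param m a [count_matrix()] with >= 2 species.
#' @param trim_m two-sided trim fraction on the log-ratios (default 0.30).
#' @param trim_a two-sided trim fraction on the absolute log-intensity
#'   (default 0.05).
#' @param ref optional reference species (name or column index);
#'   auto-selected when `NULL`.
#' @return named numeric vector of per-species factors, geometric mean 1.
#' @export
tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) < 2)
    stop("need at least 2 species", call. = FALSE)
  if (any(colSums(m$counts) == 0))
    stop("degenerate all-zero library", call. = FALSE)
  if (is.character(ref)) ref <- match(ref, colnames(m$counts))
  f <- edgeR::calcNormFactors(m$counts, lib.size = m$lib_size,
                              method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(m$counts))
}

#' Convert counts to natural-log RPKM
#'
#' `log(count * 1e9 / (length_bp * effective_library) + pseudocount)` with
#' the effective library size equal to the library size times its TMM
#' factor. With `pseudocount = 0`, zero counts map to `-Inf`; such entries
#' are expected to be rare after [filter_low_expression()] and are dropped
#' later by [standardize()].
#'
#' @param m a [count_matrix()].
#' @param factors per-species scale factors (default all ones).
#' @param pseudocount added inside the log (default 0).
#' @return an [expr_matrix()] at stage `"log_rpkm"`.
#' @export
to_log_rpkm <- function(m, factors = NULL, pseudocount = 0) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(factors)) factors <- rep(1, ncol(m$counts))
  eff <- m$lib_size * factors
  rpkm <- sweep(m$counts * 1e9, 1, m$gene_length, "/")
  rpkm <- sweep(rpkm, 2, eff, "/")
  expr_matrix(log(rpkm + pseudocount), stage = "log_rpkm")
}

#' Standardize expression gene-wise
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Rows with zero variance or non-finite values (e.g.
#' `-Inf` from zero counts without a pseudocount) cannot be standardized and
#' are dropped with a warning. Idempotent on already standardized input.
#'
#' @param e an [expr_matrix()] (or plain matrix), genes x species.
#' @return an [expr_matrix()] at stage `"standardized"`.
#' @export
standardize <- function(e) {
  v <- as.matrix(unclass(e))
  attr(v, "stage") <- NULL
  bad_finite <- !apply(v, 1, function(r) all(is.finite(r)))
  sds <- apply(v, 1, stats::sd)
  bad_const <- !bad_finite & (sds == 0 | is.na(sds))
  drop <- bad_finite | bad_const
  if (any(drop))
    warning(sum(drop), " gene(s) dropped (constant or non-finite rows): ",
            paste(utils::head(rownames(v)[drop], 5), collapse = ", "))
  v <- v[!drop, , drop = FALSE]
  z <- t(scale(t(v)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  expr_matrix(z, stage = "standardized")
}

#' Fraction of genes compatible with normality
#'
#' QC summary: the fraction of genes whose per-row Shapiro-Wilk test does
#' not reject normality at level `alpha`. No multiplicity correction is
#' applied; this is a descriptive check of the normality assumption behind
#' the downstream Gaussian models.
#'
#' @param e expression matrix, genes x species (>= 3 species).
#' @param alpha rejection level (default 0.05).
#' @return proportion in `[0, 1]`.
#' @export
normalcy_fraction <- function(e, alpha = 0.05) {
  v <- as.matrix(e)
  if (ncol(v) < 3) stop("need at least 3 species", call. = FALSE)
  p <- apply(v, 1, function(r) stats::shapiro.test(r)$p.value)
  mean(p >= alpha)
}

#' Full normalization pipeline
#'
#' Convenience wrapper: low-expression filter, TMM factors, log-RPKM with
#' effective library sizes, gene-wise standardization. The stage order is
#' fixed; see the individual steps for details.
#'
#' @param m a [count_matrix()].
#' @param min_count,min_species filter thresholds.
#' @param tmm apply the TMM correction (default TRUE).
#' @param pseudocount passed to [to_log_rpkm()].
#' @return list with `counts` (filtered), `factors`, `log_rpkm`, and
#'   `standardized`.
#' @export
normalize_counts <- function(m, min_count = 3, min_species = 3, tmm = TRUE,
                             pseudocount = 0) {
  mf <- filter_low_expression(m, min_count, min_species)
  f <- if (tmm) tmm_factors(mf) else
    stats::setNames(rep(1, ncol(mf$counts)), colnames(mf$counts))
  lr <- to_log_rpkm(mf, f, pseudocount = pseudocount)
  list(counts = mf, factors = f, log_rpkm = lr,
       standardized = suppressWarnings(standardize(lr)))
}
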