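#' Read an ortholog count table
#'
#' Expects a TSV with gene IDs in the first column, a `length_bp` column,
#' and one column of counts per species.
#'
#' @param path TSV file path.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"length_bp" %in% names(tab))
    stop("counts TSV needs a 'length_bp' column", call. = FALSE)
  gene <- tab[[1]]
  sp_cols <- setdiff(names(tab)[-1], "length_bp")
  counts <- as.matrix(tab[, sp_cols, drop = FALSE])
  rownames(counts) <- gene
  count_matrix(counts, tab$length_bp)
}

#' Write an ortholog count table
#'
#' @param m a [count_matrix()].
#' @param path output TSV path.
#' @export
write_counts_tsv <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  tab <- data.frame(gene = rownames(m$counts),
                    length_bp = as.integer(m$gene_length),
                    m$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' TSV with columns `species`, `lifespan_days`, `mass_mg` (extra columns
#' are kept).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lifespan_days") %in% names(tab)))
    stop("trait TSV needs 'species' and 'lifespan_days' columns",
         call. = FALSE)
  tab
}

#' Read a differential-expression direction table
#'
#' TSV with columns `gene` and `direction` (up/down) or `effect`
#' (pro/anti).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_de_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab) ||
      !any(c("direction", "effect") %in% names(tab)))
    stop("DE TSV needs 'gene' and 'direction' (or 'effect') columns",
         call. = FALSE)
  tab
}

#' Write an expression matrix with its stage recorded
#'
#' The processing stage is written as a `# stage:` comment on the first
#' line, so round trips through [read_expression_tsv()] preserve it.
#'
#' @param e an [expr_matrix()].
#' @param path output TSV path.
#' @export
write_expression_tsv <- function(e, path) {
  st <- expr_stage(e) %||% "log_rpkm"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", st), con)
  tab <- data.frame(gene = rownames(e), as.matrix(e), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param path TSV file written by [write_expression_tsv()].
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  stage <- if (grepl("^# stage:", first))
    trimws(sub("^# stage:", "", first)) else "log_rpkm"
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expr_matrix(m, stage)
}

#' Write a longevity-signature table
#'
#' @param x a `signature_result` from [run_signature()].
#' @param path output TSV path.
#' @export
write_signature_tsv <- function(x, path) {
  stopifnot(inherits(x, "signature_result"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
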