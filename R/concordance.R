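#' Match signature signs against differential-expression directions
#'
#' Over the intersection of gene sets, counts the genes whose signature
#' correlation sign agrees with an external direction call: positive
#' correlation matches "up" (or a pro-longevity annotation), negative
#' matches "down" (or anti-longevity).
#'
#' @param signature named vector of signs: numeric `+1`/`-1` or character
#'   `"positive"`/`"negative"`, names are gene IDs.
#' @param de data.frame with columns `gene` and `direction` (values `up` /
#'   `down`) or `effect` (values `pro` / `anti`).
#' @return list with `k_same`, `k_opp`, `n`.
#' @export
match_directions <- function(signature, de) {
  sig <- normalize_signs(signature)
  dir_col <- if ("direction" %in% names(de)) "direction"
             else if ("effect" %in% names(de)) "effect"
             else stop("'de' needs a 'direction' or 'effect' column",
                       call. = FALSE)
  dir <- tolower(as.character(de[[dir_col]]))
  updown <- ifelse(dir %in% c("up", "pro"), 1,
                   ifelse(dir %in% c("down", "anti"), -1, NA))
  if (anyNA(updown))
    stop("directions must be up/down (or pro/anti)", call. = FALSE)
  dirs <- stats::setNames(updown, de$gene)
  common <- intersect(names(sig), names(dirs))
  if (!length(common))
    stop("no genes shared between signature and DE table", call. = FALSE)
  same <- sum(sig[common] == dirs[common])
  list(k_same = same, k_opp = length(common) - same, n = length(common))
}

normalize_signs <- function(signature) {
  if (is.character(signature)) {
    s <- ifelse(tolower(signature) %in% c("positive", "+", "up"), 1,
                ifelse(tolower(signature) %in% c("negative", "-", "down"),
                       -1, NA))
  } else {
    s <- sign(as.numeric(signature))
  }
  if (anyNA(s) || any(s == 0))
    stop("signature signs must be strictly positive or negative",
         call. = FALSE)
  stats::setNames(s, names(signature))
}

#' One-sided exact binomial tail for a concordance count
#'
#' \eqn{P(X \ge k \mid n, 1/2) = \sum_{i=k}^{n} \binom{n}{i} 2^{-n}}:
#' the chance of observing at least `k_same` same-direction genes out of
#' `n` when matches and mismatches are equally likely.
#'
#' @param k_same number of same-direction genes (`0 <= k_same <= n`).
#' @param n total genes compared (>= 1).
#' @return exact upper-tail probability.
#' @export
binomial_tail_p <- function(k_same, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k_same < 0 || k_same > n)
    stop("k_same must lie in [0, n]", call. = FALSE)
  stats::pbinom(k_same - 1, n, 0.5, lower.tail = FALSE)
}

#' Permutation p-value for direction concordance
#'
#' Null distribution by relabeling: the signature's sign labels are
#' permuted across its genes (sampling without replacement) `B` times; for
#' each permutation the same-direction count and its binomial tail are
#' recomputed, and the permutation p-value is
#' `(1 + #\{replicates with p <= observed\}) / (B + 1)`.
#'
#' @inheritParams match_directions
#' @param B number of permutations (default 1000).
#' @param seed RNG seed (optional).
#' @return permutation p-value in `(0, 1]`.
#' @export
permutation_p <- function(signature, de, B = 1000, seed = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  sig <- normalize_signs(signature)
  obs <- match_directions(sig, de)
  p_obs <- binomial_tail_p(obs$k_same, obs$n)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- stats::setNames(sample(sig), names(sig))
    mb <- match_directions(perm, de)
    if (binomial_tail_p(mb$k_same, mb$n) <= p_obs) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' Direction-concordance test
#'
#' Full concordance result for one comparison: same/opposite counts over
#' the shared genes, percent matching (rounded half away from zero), the
#' exact binomial tail, and (optionally) the permutation p-value.
#'
#' @inheritParams permutation_p
#' @param permute also compute the permutation p-value (default TRUE).
#' @return list of class `concordance_result`: `k_same`, `k_opp`, `n`,
#'   `percent`, `p_binom`, `p_perm` (NA when `permute = FALSE`), `B`.
#' @export
concordance_test <- function(signature, de, B = 1000, seed = NULL,
                             permute = TRUE) {
  m <- match_directions(signature, de)
  res <- concordance_from_counts(m$k_same, m$k_opp)
  res$p_perm <- if (permute) permutation_p(signature, de, B, seed)
                else NA_real_
  res$B <- if (permute) B else 0L
  res
}

#' Concordance result from printed counts
#'
#' Builds a `concordance_result` directly from a (same, opposite) tally,
#' e.g. when reproducing published comparison tables whose underlying gene
#' lists are not available.
#'
#' @param k_same,k_opp same- and opposite-direction counts.
#' @return list of class `concordance_result` (without permutation p).
#' @export
concordance_from_counts <- function(k_same, k_opp) {
  n <- k_same + k_opp
  structure(list(k_same = k_same, k_opp = k_opp, n = n,
                 percent = floor(100 * k_same / n + 0.5),
                 p_binom = binomial_tail_p(k_same, n),
                 p_perm = NA_real_, B = 0L),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Concordance:", x$k_same, "same /", x$k_opp, "opposite (",
      x$percent, "% matching)\n")
  cat("  binomial p =", format(x$p_binom, digits = 3))
  if (!is.na(x$p_perm)) cat(", permutation p =", format(x$p_perm, digits = 3),
                            "(B =", x$B, ")")
  cat("\n")
  invisible(x)
}

#' Summarize a set of concordance results
#'
#' @param results list of `concordance_result` objects.
#' @param alpha significance level (default 0.05).
#' @return list with `n_total`, `n_significant` (binomial p < alpha),
#'   `p_range` and `percent_range` among the significant comparisons
#'   (NULL when none are significant).
#' @export
summarize_concordance <- function(results, alpha = 0.05) {
  if (!length(results)) stop("empty result list", call. = FALSE)
  p <- vapply(results, function(r) r$p_binom, numeric(1))
  pct <- vapply(results, function(r) r$percent, numeric(1))
  sig <- p < alpha
  list(n_total = length(results), n_significant = sum(sig),
       p_range = if (any(sig)) range(p[sig]) else NULL,
       percent_range = if (any(sig)) range(pct[sig]) else NULL)
}

#' Published lifespan-intervention comparison tallies
#'
#' Same/opposite direction counts from eleven published microarray
#' experiments in which fly lifespan was extended by dietary or genetic
#' intervention (GEO accessions in the table), each compared against a
#' cross-species longevity signature. Shipped as plain text under
#' `extdata`; useful for exercising the concordance statistics on real
#' tallies without any downloads.
#'
#' @return data.frame with columns `accession`, `tissue`, `strain`,
#'   `treatment`, `same`, `opposite`.
#' @export
microarray_comparisons <- function() {
  path <- system.file("extdata", "microarray_concordance.tsv",
                      package = "longsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Curated longevity-database direction matches
#'
#' Signature correlation signs and curated longevity effects (pro / anti)
#' for 18 genes found in longevity-gene databases, for the sign-agreement
#' test: positive correlation is expected to pair with pro-longevity
#' effects and negative with anti-longevity.
#'
#' @return data.frame with columns `gene`, `sign`, `organism`, `symbol`,
#'   `effect`.
#' @export
longevity_db_matches <- function() {
  path <- system.file("extdata", "longevity_db_directions.tsv",
                      package = "longsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
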