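#' Pairwise expression divergence versus divergence time
#'
#' For every unordered pair of species, the divergence time `x` (age of the
#' pair's most recent common ancestor on the calibrated tree, My) and the
#' expression divergence `y`: the mean over genes of the two-value sample
#' variance of the pair's standardized values, i.e. `(e_i - e_j)^2 / 2`
#' averaged over genes.
#'
#' @param e standardized expression matrix, genes x species. A plain matrix
#'   is accepted; an [expr_matrix()] must be at the `"standardized"` stage.
#' @param tree rooted ultrametric `phylo` containing all species.
#' @return data.frame with columns `species_a`, `species_b`, `x_my`, `y`
#'   (one row per pair, `n (n - 1) / 2` rows).
#' @export
divergence_points <- function(e, tree) {
  v <- as.matrix(e)
  st <- expr_stage(e)
  if (!is.null(st) && st != "standardized")
    stop("expression must be at the standardized stage", call. = FALSE)
  sp <- colnames(v)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ages <- mrca_age_matrix(tree)[sp, sp]
  pairs <- utils::combn(sp, 2)
  y <- apply(pairs, 2, function(p) mean((v[, p[1]] - v[, p[2]])^2) / 2)
  x <- apply(pairs, 2, function(p) ages[p[1], p[2]])
  data.frame(species_a = pairs[1, ], species_b = pairs[2, ],
             x_my = x, y = y, stringsAsFactors = FALSE)
}

#' Fit the selection/drift divergence-plateau model
#'
#' Least-squares fit of
#' \deqn{y = \frac{\sigma^2}{2\alpha}\left(1 - e^{-2\alpha x}\right)}
#' to divergence points: under stabilizing selection of strength
#' \eqn{\alpha} and drift variance \eqn{\sigma^2}, pairwise expression
#' divergence saturates at the plateau \eqn{\sigma^2 / (2\alpha)}; in the
#' \eqn{\alpha \to 0} limit the curve degenerates to the Brownian-motion
#' line \eqn{y = \sigma^2 x}. The drift parameter is profiled in closed
#' form for each \eqn{\alpha} (the model is linear in \eqn{\sigma^2}), and
#' \eqn{\alpha} is found by bounded search on the log scale from several
#' log-spaced starting intervals. Fits with \eqn{\hat\alpha < 10^{-6}} are
#' reported as the BM limit with \eqn{\hat\sigma^2} from the straight-line
#' fit.
#'
#' @param points data.frame from [divergence_points()] (columns `x_my`,
#'   `y`), or any data.frame with those columns; >= 3 distinct `x` values.
#' @param n_starts number of log-spaced search intervals for alpha.
#' @return object of class `plateau_fit`: `alpha`, `sigma2`, `asymptote`
#'   (`sigma2 / (2 alpha)`, `Inf` in the BM limit), `rss`, `n_points`,
#'   `bm_limit` flag.
#' @export
fit_plateau <- function(points, n_starts = 5) {
  x <- points$x_my
  y <- points$y
  if (length(unique(x)) < 3)
    stop("need >= 3 points with distinct divergence times", call. = FALSE)
  g <- function(a) (1 - exp(-2 * a * x)) / (2 * a)
  rss_of <- function(a) {
    ga <- g(a)
    s2 <- sum(y * ga) / sum(ga^2)
    sum((y - s2 * ga)^2)
  }
  lo <- log(1e-8)
  hi <- log(200 / max(x))
  cuts <- seq(lo, hi, length.out = n_starts + 1)
  best <- NULL
  for (s in seq_len(n_starts)) {
    opt <- stats::optimize(function(la) rss_of(exp(la)),
                           interval = cuts[s:(s + 1)], tol = 1e-12)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  alpha <- exp(best$minimum)
  # BM limit: compare against the straight line through the origin
  s2_line <- sum(x * y) / sum(x^2)
  rss_line <- sum((y - s2_line * x)^2)
  if (alpha < 1e-6 || rss_line <= best$objective) {
    return(structure(list(alpha = 0, sigma2 = s2_line, asymptote = Inf,
                          rss = rss_line, n_points = length(x),
                          bm_limit = TRUE),
                     class = "plateau_fit"))
  }
  ga <- g(alpha)
  sigma2 <- sum(y * ga) / sum(ga^2)
  structure(list(alpha = alpha, sigma2 = sigma2,
                 asymptote = sigma2 / (2 * alpha), rss = best$objective,
                 n_points = length(x), bm_limit = FALSE),
            class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("Divergence-plateau fit (", x$n_points, " species pairs)\n", sep = "")
  if (x$bm_limit) {
    cat("  BM limit: y = sigma2 * x, sigma2 =", signif(x$sigma2, 4), "\n")
  } else {
    cat("  alpha  =", signif(x$alpha, 4), "per My\n")
    cat("  sigma2 =", signif(x$sigma2, 4), "per My\n")
    cat("  asymptote sigma2/(2 alpha) =", signif(x$asymptote, 4), "\n")
  }
  if (!is.null(x$ci_alpha))
    cat("  95% CI alpha:", paste(signif(x$ci_alpha, 4), collapse = " - "),
        " sigma2:", paste(signif(x$ci_sigma2, 4), collapse = " - "), "\n")
  if (!is.null(x$jackknife_alpha))
    cat("  jackknife alpha range:",
        paste(signif(x$jackknife_alpha, 4), collapse = " - "), "\n")
  invisible(x)
}

#' Evaluate the plateau curve
#'
#' @param fit a `plateau_fit`.
#' @param x divergence times (My).
#' @return predicted divergence values.
#' @export
predict_plateau <- function(fit, x) {
  if (fit$bm_limit) fit$sigma2 * x
  else fit$sigma2 / (2 * fit$alpha) * (1 - exp(-2 * fit$alpha * x))
}

#' Plateau fit with bootstrap confidence intervals and species jackknife
#'
#' Point fit of the plateau model plus two uncertainty analyses: (i) a
#' gene bootstrap -- resample genes with replacement `B` times, recompute
#' the divergence points and refit, report percentile 95% intervals for
#' both parameters; (ii) a species jackknife -- remove each species in
#' turn, refit, and report the range of the selection parameter across the
#' leave-one-out fits. Replicates whose refit fails are dropped and
#' counted.
#'
#' @param e standardized expression matrix, genes x species.
#' @param tree rooted ultrametric `phylo`.
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a `plateau_fit` with added `ci_alpha`, `ci_sigma2` (percentile
#'   bounds), `jackknife_alpha`, `jackknife_sigma2` (min/max over species
#'   removals), `n_failed` (dropped replicates), `B`.
#' @export
plateau_uncertainty <- function(e, tree, B = 1000, seed = NULL) {
  v <- as.matrix(e)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  fit <- fit_plateau(divergence_points(v, tree))
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(v)
  boot <- matrix(NA_real_, B, 2)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(ng, ng, replace = TRUE)
    fb <- try(fit_plateau(divergence_points(v[idx, , drop = FALSE], tree)),
              silent = TRUE)
    if (inherits(fb, "try-error")) failed <- failed + 1L
    else boot[b, ] <- c(fb$alpha, fb$sigma2)
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  fit$ci_alpha <- unname(stats::quantile(boot[, 1], c(0.025, 0.975)))
  fit$ci_sigma2 <- unname(stats::quantile(boot[, 2], c(0.025, 0.975)))
  jack <- t(vapply(colnames(v), function(sp) {
    keep <- setdiff(colnames(v), sp)
    tr <- ape::keep.tip(tree, keep)
    fj <- fit_plateau(divergence_points(v[, keep, drop = FALSE], tr))
    c(fj$alpha, fj$sigma2)
  }, numeric(2)))
  fit$jackknife_alpha <- range(jack[, 1])
  fit$jackknife_sigma2 <- range(jack[, 2])
  fit$n_failed <- failed
  fit$B <- B
  fit
}
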