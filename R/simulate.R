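#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' describe the study conditions the pipeline is designed for: 14 species
#' on a 56-My tree, 6,510 ortholog sets, a small signature fraction, an
#' 85/15 OU/BM gene mix, and selection/drift strengths matching the
#' divergence-plateau fit of the real data (alpha = 0.0673 per My,
#' sigma2 = 0.142 per My).
#'
#' @param n_species number of species (>= 3).
#' @param tree_depth root-to-tip depth in My.
#' @param n_genes number of ortholog sets.
#' @param signature_fraction proportion of genes tied to lifespan.
#' @param effect_size target squared correlation (R^2) between a signature
#'   gene's standardized expression and the standardized log lifespan.
#' @param gene_model_mix named proportions for the `bm` and `ou` generating
#'   models of null-gene evolution.
#' @param alpha_sim OU selection strength per My (> 0).
#' @param sigma2_sim drift variance per My (> 0).
#' @param lifespan_optimum_days OU optimum for median lifespan.
#' @param mass_optimum_mg OU optimum for body mass.
#' @param library_sizes per-species read totals (recycled; default 2e7).
#' @param mean_gene_length_bp log-normal location for simulated transcript
#'   lengths.
#' @param concordance_q probability that a simulated DE direction agrees
#'   with the signature sign.
#' @param overdispersion negative-binomial overdispersion of the count
#'   noise (0 = Poisson).
#' @param seed root RNG seed; per-operation streams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 14, tree_depth = 56, n_genes = 6510,
                       signature_fraction = 0.06, effect_size = 0.5,
                       gene_model_mix = c(bm = 0.15, ou = 0.85),
                       alpha_sim = 0.0673, sigma2_sim = 0.142,
                       lifespan_optimum_days = 25, mass_optimum_mg = 1,
                       library_sizes = 2e7, mean_gene_length_bp = 1500,
                       concordance_q = 0.63, overdispersion = 0,
                       seed = 1) {
  stopifnot(n_species >= 3, tree_depth > 0, n_genes >= 1,
            signature_fraction >= 0, signature_fraction <= 1,
            effect_size >= 0, effect_size < 1,
            alpha_sim > 0, sigma2_sim > 0,
            concordance_q >= 0, concordance_q <= 1,
            all(library_sizes > 0), overdispersion >= 0)
  mix <- gene_model_mix / sum(gene_model_mix)
  if (!all(sort(names(mix)) == c("bm", "ou")))
    stop("gene_model_mix needs proportions named 'bm' and 'ou'",
         call. = FALSE)
  structure(list(n_species = n_species, tree_depth = tree_depth,
                 n_genes = n_genes, signature_fraction = signature_fraction,
                 effect_size = effect_size, gene_model_mix = mix,
                 alpha_sim = alpha_sim, sigma2_sim = sigma2_sim,
                 lifespan_optimum_days = lifespan_optimum_days,
                 mass_optimum_mg = mass_optimum_mg,
                 library_sizes = library_sizes,
                 mean_gene_length_bp = mean_gene_length_bp,
                 concordance_q = concordance_q,
                 overdispersion = overdispersion, seed = seed),
            class = "sim_config")
}

# Derive a deterministic per-operation sub-seed from the root seed, so the
# generators are independent pure functions of (inputs, seed).
substream_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule tree rescaled to a fixed root-to-tip depth: the simplest ultrametric
#' branching process, depth-calibrated like a time tree.
#'
#' @param n_taxa number of tips (>= 3).
#' @param depth root-to-tip depth (My).
#' @param seed RNG seed.
#' @return ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
generate_tree <- function(n_taxa, depth, seed = 1) {
  if (n_taxa < 3) stop("n_taxa must be >= 3", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  set.seed(substream_seed(seed, "tree"))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * depth / tree_depth(tr)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tr
}

# Draw one or more tip-value vectors from N(mean, V) via Cholesky.
rmvn_tips <- function(n_draws, mean, V) {
  L <- chol(V)
  z <- matrix(stats::rnorm(n_draws * nrow(V)), n_draws, nrow(V))
  sweep(z %*% L, 2, mean, "+")
}

#' Simulate life-history traits on a tree
#'
#' Log median lifespan evolves under a stationary OU process around
#' `log(lifespan_optimum_days)` with the configured selection strength and
#' drift variance (stationary tip covariance
#' `sigma2/(2 alpha) exp(-alpha d_ij)`), then is exponentiated to days.
#' Log body mass follows the lifespan deviations with coefficient 0.5 plus
#' its own OU noise, reproducing the positive mass-lifespan association
#' typical of such data.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return data.frame with `species`, `lifespan_days`, `mass_mg`.
#' @export
generate_traits <- function(tree, config, seed = config$seed) {
  if (length(tree$tip.label) < 3) stop("need >= 3 taxa", call. = FALSE)
  set.seed(substream_seed(seed, "traits"))
  V <- covariance_matrix(tree, cov_model("ou", sigma2 = config$sigma2_sim,
                                         alpha = config$alpha_sim))
  log_ls <- drop(rmvn_tips(1, rep(log(config$lifespan_optimum_days),
                                  nrow(V)), V))
  dev <- log_ls - log(config$lifespan_optimum_days)
  log_mass <- log(config$mass_optimum_mg) + 0.5 * dev +
    drop(rmvn_tips(1, rep(0, nrow(V)), 0.25 * V))
  data.frame(species = tree$tip.label,
             lifespan_days = exp(log_ls), mass_mg = exp(log_mass),
             stringsAsFactors = FALSE)
}

#' Simulate expression with a planted longevity signature
#'
#' Null genes evolve on the tree under their assigned model (BM with the
#' configured drift variance, or stationary OU with the configured
#' selection and drift strengths) and are standardized gene-wise.
#' Signature genes are built in standardized space as
#' `sqrt(effect_size) * sign * z + sqrt(1 - effect_size) * eta`, where `z`
#' is the standardized log lifespan and `eta` is tree-structured noise of
#' the same kind as the null genes, orthogonalized against `z` in-sample so
#' that each signature gene's realized squared correlation with the trait
#' equals `effect_size` exactly. An unstandardized log-RPKM matrix is
#' emitted alongside (per-gene baselines and scales drawn log-normally),
#' for feeding the count generator.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param traits data.frame from [generate_traits()] covering all tips.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `standardized` ([expr_matrix()]), `log_rpkm`
#'   ([expr_matrix()]), and `truth` (data.frame `gene`, `label`
#'   in {null, signature_positive, signature_negative}, `model`
#'   in {bm, ou}, `beta_true`).
#' @export
generate_expression <- function(tree, traits, config, seed = config$seed) {
  labs <- tree$tip.label
  if (!all(labs %in% traits$species))
    stop("traits must cover all tree taxa", call. = FALSE)
  set.seed(substream_seed(seed, "expression"))
  ng <- config$n_genes
  ns <- length(labs)
  n_sig <- round(config$signature_fraction * ng)
  if (n_sig < 1 && config$effect_size > 0 && config$signature_fraction > 0)
    warning("signature_fraction * n_genes < 1: no signature genes emitted")

  z <- standardize_trait(stats::setNames(
    traits$lifespan_days[match(labs, traits$species)], labs))

  Vbm <- config$sigma2_sim * shared_path_matrix(tree)
  Vou <- covariance_matrix(tree, cov_model("ou", sigma2 = config$sigma2_sim,
                                           alpha = config$alpha_sim))
  Lbm <- chol(Vbm)
  Lou <- chol(Vou)

  model <- sample(c("bm", "ou"), ng, replace = TRUE,
                  prob = config$gene_model_mix[c("bm", "ou")])
  sig_idx <- if (n_sig >= 1) sample.int(ng, n_sig) else integer(0)
  sig_sign <- rep_len(c(1, -1), length(sig_idx))

  raw <- matrix(NA_real_, ng, ns, dimnames = list(sprintf("g%05d", 1:ng),
                                                  labs))
  zmat <- matrix(stats::rnorm(ng * ns), ng, ns)
  raw[model == "bm", ] <- zmat[model == "bm", , drop = FALSE] %*% Lbm
  raw[model == "ou", ] <- zmat[model == "ou", , drop = FALSE] %*% Lou

  std <- t(scale(t(raw)))
  e <- config$effect_size
  for (j in seq_along(sig_idx)) {
    i <- sig_idx[j]
    eta <- std[i, ]
    # remove the in-sample trait component, keep the tree-structured rest
    eta <- eta - mean(eta) - stats::cov(eta, z) / stats::var(z) * (z - 0)
    sd_eta <- stats::sd(eta)
    if (sd_eta < 1e-12) eta <- stats::rnorm(ns) else eta <- eta / sd_eta
    g <- sqrt(e) * sig_sign[j] * z + sqrt(1 - e) * eta
    std[i, ] <- (g - mean(g)) / stats::sd(g)
  }

  # map to an unstandardized log-RPKM scale for the count generator
  mu_g <- stats::rnorm(ng, mean = 2, sd = 1.2)
  sd_g <- exp(stats::rnorm(ng, mean = log(0.5), sd = 0.4))
  log_rpkm <- sweep(sweep(std, 1, sd_g, "*"), 1, mu_g, "+")

  label <- rep("null", ng)
  label[sig_idx] <- ifelse(sig_sign > 0, "signature_positive",
                           "signature_negative")
  beta <- rep(0, ng)
  beta[sig_idx] <- sig_sign * sqrt(e)
  truth <- data.frame(gene = rownames(raw), label = label, model = model,
                      beta_true = beta, stringsAsFactors = FALSE)
  list(standardized = expr_matrix(std, "standardized"),
       log_rpkm = expr_matrix(log_rpkm, "log_rpkm"),
       truth = truth)
}

#' Convert log-RPKM expression to read counts
#'
#' Inverse of the RPKM transform with sampling noise: counts are drawn with
#' mean `exp(logRPKM) * (length_bp / 1e3) * (library_size / 1e6)`, Poisson
#' by default or negative binomial when an overdispersion is given.
#'
#' @param expr log-RPKM matrix (genes x species).
#' @param lengths positive gene lengths in bp (one per gene).
#' @param library_sizes positive per-species read totals (recycled).
#' @param seed RNG seed.
#' @param overdispersion NB overdispersion (variance = mu + od * mu^2);
#'   0 gives Poisson noise.
#' @return a [count_matrix()] with the supplied `library_sizes`.
#' @export
expression_to_counts <- function(expr, lengths, library_sizes, seed = 1,
                                 overdispersion = 0) {
  v <- as.matrix(expr)
  if (any(lengths <= 0) || any(library_sizes <= 0))
    stop("lengths and library sizes must be positive", call. = FALSE)
  lengths <- rep_len(lengths, nrow(v))
  library_sizes <- rep_len(library_sizes, ncol(v))
  set.seed(substream_seed(seed, "counts"))
  mu <- exp(v) * outer(lengths / 1e3, library_sizes / 1e6)
  counts <- if (overdispersion > 0)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion),
           nrow(v), ncol(v))
  else
    matrix(stats::rpois(length(mu), mu), nrow(v), ncol(v))
  dimnames(counts) <- dimnames(v)
  count_matrix(counts, lengths, library_sizes)
}

#' Simulate a differential-expression direction table
#'
#' Samples `n` signature genes without replacement and assigns each an
#' up/down direction: with probability `q` the direction agrees with the
#' gene's signature sign (positive <-> up), otherwise it is flipped.
#'
#' @param truth ground-truth table from [generate_expression()].
#' @param q agreement probability in `[0, 1]`.
#' @param n number of genes to select (at most the number of signature
#'   genes).
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `direction`.
#' @export
generate_de_table <- function(truth, q, n, seed = 1) {
  sig <- truth[truth$label != "null", ]
  if (n > nrow(sig))
    stop("n exceeds the number of signature genes", call. = FALSE)
  set.seed(substream_seed(seed, "de_table"))
  pick <- sig[sample.int(nrow(sig), n), ]
  expected <- ifelse(pick$beta_true > 0, "up", "down")
  flip <- stats::runif(n) >= q
  direction <- ifelse(flip, ifelse(expected == "up", "down", "up"), expected)
  data.frame(gene = pick$gene, direction = direction,
             stringsAsFactors = FALSE)
}

#' Simulate expression directly under the divergence model
#'
#' Gene vectors drawn from the stationary OU process (or BM) on the tree
#' with the given selection and drift strengths, emitted on the
#' standardized scale without per-row renormalization: under the
#' generating parameters of interest the stationary variance
#' `sigma2 / (2 alpha)` is close to 1, and renormalizing each row by its
#' finite-sample SD would bias the divergence-plateau scale. Used for
#' parameter-recovery experiments and for plotting OU versus BM divergence
#' trajectories.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param alpha OU selection strength per My (ignored for `model = "bm"`).
#' @param sigma2 drift variance per My.
#' @param n_genes number of gene vectors.
#' @param seed RNG seed.
#' @param model `"ou"` (stationary) or `"bm"`.
#' @return [expr_matrix()] at the `"standardized"` stage, genes x species.
#' @export
simulate_divergence_profile <- function(tree, alpha, sigma2, n_genes,
                                        seed = 1, model = c("ou", "bm")) {
  model <- match.arg(model)
  set.seed(substream_seed(seed, "divergence"))
  V <- if (model == "ou")
    covariance_matrix(tree, cov_model("ou", sigma2 = sigma2, alpha = alpha))
  else sigma2 * shared_path_matrix(tree)
  m <- rmvn_tips(n_genes, rep(0, nrow(V)), V)
  dimnames(m) <- list(sprintf("g%05d", seq_len(n_genes)), tree$tip.label)
  expr_matrix(m, "standardized")
}

#' Run the full synthetic-data generator
#'
#' Tree (or the packaged fixture), traits, expression with ground truth,
#' counts, and a DE direction table, all derived from one root seed.
#'
#' @param config a [sim_config()].
#' @param tree optional tree; defaults to [drosophila_tree()] when
#'   `config$n_species == 14`, else a [generate_tree()] draw.
#' @param n_de number of genes in the DE table (default: all signature
#'   genes).
#' @return list with `tree`, `traits`, `expression` (list from
#'   [generate_expression()]), `counts`, `de_table`, `config`.
#' @export
simulate_study <- function(config = sim_config(), tree = NULL, n_de = NULL) {
  if (is.null(tree)) {
    tree <- if (config$n_species == 14) drosophila_tree()
            else generate_tree(config$n_species, config$tree_depth,
                               config$seed)
  }
  traits <- generate_traits(tree, config)
  expr <- generate_expression(tree, traits, config)
  set.seed(substream_seed(config$seed, "lengths"))
  lengths <- pmax(200, round(stats::rlnorm(config$n_genes,
                                           log(config$mean_gene_length_bp),
                                           0.6)))
  counts <- expression_to_counts(expr$log_rpkm, lengths,
                                 rep_len(config$library_sizes,
                                         length(tree$tip.label)),
                                 seed = config$seed,
                                 overdispersion = config$overdispersion)
  n_sig <- sum(expr$truth$label != "null")
  if (is.null(n_de)) n_de <- n_sig
  de <- if (n_de >= 1 && n_sig >= n_de)
    generate_de_table(expr$truth, config$concordance_q, n_de, config$seed)
  else NULL
  list(tree = tree, traits = traits, expression = expr, counts = counts,
       de_table = de, config = config)
}

#' Write a simulated study to disk
#'
#' Emits the standard plain-text artifacts: counts TSV (gene rows, species
#' columns, plus a `length_bp` column), trait TSV, Newick tree, DE TSV,
#' and ground-truth TSV.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             traits = file.path(dir, "traits.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_counts_tsv(study$counts, paths["counts"])
  utils::write.table(study$traits, paths["traits"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(study$tree, paths["tree"])
  utils::write.table(study$expression$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$de_table)) {
    paths["de"] <- file.path(dir, "de_table.tsv")
    utils::write.table(study$de_table, paths["de"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
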