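# longsig

Cross-species transcriptomic signatures of longevity.

Related species differ several-fold in lifespan, and part of that
difference may be visible in gene expression. `longsig` takes a
gene-by-species ortholog read-count matrix, a time-calibrated phylogeny
(Newick, branch lengths in million years), and a life-history trait
table, and answers three questions:

1. **How does expression diverge?** Neighbor-joining expression
   phylograms from `1 − ρ_Spearman` distances with gene-bootstrap branch
   support, and a selection/drift fit of pairwise expression divergence
   *y* against divergence time *x*:

   *y* = σ²/(2α) · (1 − e^(−2αx)),

   where α is the strength of stabilizing selection (per My), σ² the
   drift variance (per My), and σ²/(2α) the divergence plateau; α → 0
   recovers the Brownian line *y* = σ²x. Confidence intervals come from
   a gene bootstrap, robustness from a species jackknife. Per-gene
   classification complements this: Pagel's λ and Blomberg's K
   phylogenetic signals, and likelihood-ratio tests of Brownian motion
   against Ornstein–Uhlenbeck models with one to three selective optima
   painted from the taxonomy.

2. **Which genes track lifespan?** Phylogenetic generalized least
   squares per gene: standardized expression regressed on standardized
   log median lifespan under four residual-covariance models (Null, BM,
   Pagel's λ, stationary OU), structure parameters estimated jointly
   with the coefficients by maximum likelihood, best model selected by
   likelihood, Benjamini–Hochberg FDR attached — the ranked *longevity
   signature* with correlation signs.

3. **Does the signature agree with interventions?** Direction
   concordance of signature signs against differential-expression tables
   from lifespan-extending interventions (or curated pro-/anti-longevity
   annotations): exact one-sided binomial tails at p = ½ and
   label-permutation p-values.

Counts are prepared by the standard chain — low-expression filter
(< 3 counts in ≥ 3 species), TMM scale factors, natural-log RPKM,
gene-wise standardization — and a fully seeded synthetic-data generator
produces trees, traits, expression with a planted signature, counts, and
DE tables with ground-truth labels for calibration and recovery testing.
A 14-species, 56-My *Drosophila* fixture tree is included.

## Worked example

Simulate a study at the packaged scale, normalize, and run the three
stages:

```r
library(longsig)
tree  <- drosophila_tree()
study <- simulate_study(sim_config(n_genes = 2000, seed = 42))
norm  <- normalize_counts(study$counts)

fit <- plateau_uncertainty(norm$standardized, tree, B = 200, seed = 1)
fit
#> Divergence-plateau fit (91 species pairs)
#>   alpha  = 0.05692 per My
#>   sigma2 = 0.1229 per My
#>   asymptote sigma2/(2 alpha) = 1.079
#>   95% CI alpha: 0.05271 - 0.06127  sigma2: 0.1149 - 0.1312
#>   jackknife alpha range: 0.05535 - 0.05958

sig <- run_signature(norm$standardized, study$traits, tree,
                     exclude = "Dvir")
sig
#> Longevity signature: 1992 genes; 253 with p < 0.05 ( 128 with p < 0.01)
#> retained after excluding Dvir : 84 % of hits

res <- concordance_test(signature_signs(sig), study$de_table,
                        B = 1000, seed = 1)
res
#> Concordance: 69 same / 48 opposite ( 59 % matching)
#>   binomial p = 0.032, permutation p = 0.0509 (B = 1000 )
```

Reading the output: the divergence plateau at ≈ 1.08 (standardized
units) with α̂ ≈ 0.057/My says pairwise expression divergence saturates
instead of growing linearly — stabilizing selection dominates drift at
this depth; the bootstrap CI excludes zero and the jackknife range shows
no single species drives the fit. The signature table ranks genes by
best-model slope p-value; 84% of hits survive removal of the long-lived
outgroup. The concordance test finds 59% of the simulated intervention
DE directions agreeing with the signature signs (the generator's
agreement probability defaults to 0.63), significant by the exact
binomial tail and borderline by permutation.

Published comparison tallies are shipped for the concordance
statistics:

```r
tab <- microarray_comparisons()
res <- lapply(seq_len(nrow(tab)), function(i)
  concordance_from_counts(tab$same[i], tab$opposite[i]))
summarize_concordance(res)
#> $n_total
#> [1] 11
#> $n_significant
#> [1] 9
#> $p_range
#> [1] 4.897865e-06 2.915597e-02
#> $percent_range
#> [1] 58 69
```

A thin command-line wrapper over these functions is installed at
`inst/cli/longsig.R` (subcommands `simulate`, `normalize`, `phylogram`,
`divergence`, `pgls`, `concord`).

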