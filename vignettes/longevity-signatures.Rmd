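---
title: "Methods: cross-species longevity signatures from comparative transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species longevity signatures from comparative transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsig)
```

## The problem

Median lifespan varies several-fold even among closely related species.
If some of that variation is encoded in gene regulation, genes whose
expression tracks lifespan across a clade are candidate longevity
correlates. Detecting them is not a matter of running one correlation per
gene: species are not independent observations. Related species share
most of their evolutionary history, so both expression and lifespan are
phylogenetically autocorrelated, and naive per-gene regressions reject
far too often. `longsig` implements the full analysis chain for this
problem on a gene-by-species ortholog count matrix, a time-calibrated
phylogeny, and a table of life-history traits — the setting it was built
for is a 14-species *Drosophila* whole-body RNA-seq comparison with a
56-My root, and the packaged fixture tree reproduces that scale.

## Normalization

Counts pass through a fixed stage order: low-expression filter, TMM
scale factors, log-RPKM, gene-wise standardization.

* **Filter** (`filter_low_expression`): a gene is removed when
  `min_species` (default 3) or more species have fewer than `min_count`
  (default 3) reads. The rule is applied to raw counts, before
  normalization, so it is independent of scale factors.
* **TMM** (`tmm_factors`): the trimmed mean of M-values, computed by
  `edgeR::calcNormFactors` with the conventional 30% trim on log-ratios
  and 5% on absolute log-intensity, reference library auto-selected by
  the upper-quartile rule, factors rescaled to unit geometric mean. The
  test suite cross-checks the factors against an independently coded
  brute-force implementation of the doubly-trimmed weighted mean.
* **log-RPKM** (`to_log_rpkm`): `ln(count * 1e9 / (length_bp *
  effective_library))`, with the effective library equal to library size
  times its TMM factor. Whether RPKM should use TMM-adjusted effective
  libraries or raw totals is a genuine ambiguity; effective libraries
  are the default and plain totals are available by passing unit
  factors. The pseudocount defaults to 0 — zeros become `-Inf` and the
  affected genes are dropped at standardization, which after the filter
  is a rare event; a small positive pseudocount is available for
  zero-heavy synthetic edge cases.
* **Standardization** (`standardize`): each gene to mean 0, sample SD 1
  (n − 1). Cross-species comparisons downstream all operate on this
  scale, so only relative expression profiles matter.
* **QC** (`normalcy_fraction`): the fraction of genes whose per-row
  Shapiro–Wilk test retains normality at α = 0.05, reported without
  multiplicity correction — it is a descriptive summary of how well the
  Gaussian working assumption fits, not an inference.

## Expression phylograms

`expression_distance` computes 1 minus the Spearman correlation between
species profiles (average ranks on ties, which matters for
count-derived data); `neighbor_joining` wraps the standard Saitou–Nei
agglomeration and resolves the occasional negative branch length by
clamping it to zero and moving the deficit to a sibling edge, which
preserves path lengths through the joined node. `bootstrap_support`
resamples genes with replacement, rebuilds the tree each time, and
scores each internal edge by the fraction of replicates containing the
same bipartition (branch lengths ignored; ties in the NJ criterion are
broken deterministically by the underlying implementation, and supports
are invariant to gene order). Whether to bootstrap standardized or raw
log-RPKM values is not dictated by the method; standardized values are
the default since they are what every downstream stage consumes.

## The divergence plateau

For each pair of species, divergence is the mean over genes of the
two-point sample variance of their standardized values,
`(e_i - e_j)^2 / 2`, plotted against the age `x` of the pair's most
recent common ancestor (not the patristic distance — the natural axis
for a time-calibrated, ultrametric tree). Under drift alone divergence
grows linearly; under stabilizing selection it saturates. The fitted
model is

$$y = \frac{\sigma^2}{2\alpha}\left(1 - e^{-2\alpha x}\right),$$

with selection strength α (per My) and drift variance σ² (per My); the
asymptote is σ²/(2α), and the α → 0 limit is the Brownian line y = σ²x.
The model is linear in σ² once α is fixed, so `fit_plateau` profiles σ²
in closed form and searches α on the log scale over five log-spaced
intervals with tight tolerance; fits driven below α = 10⁻⁶ are reported
as the BM limit. `plateau_uncertainty` adds percentile 95% intervals
from a gene bootstrap (resampling rows, default B = 1000) and a species
jackknife reporting the min–max range of α across leave-one-out refits.

The divergence denominator (two-value sample variance, denominator 1)
is one of two defensible readings of "pairwise expression variance";
it is the one that makes `y` equal to half the squared difference and
the asymptote directly comparable to the stationary OU variance.

## Per-gene evolutionary models and signals

`covariance_matrix` builds the four residual structures used
throughout: independence (σ²I), Brownian motion (σ² times shared branch
length), Pagel's λ (off-diagonals of BM scaled by λ ∈ [0,1]), and
stationary Ornstein–Uhlenbeck (σ²/(2α) · e^{−α d}, patristic distance
d). The stationary OU convention was chosen over the non-stationary
Hansen conditioning because it is the common regression default and, on
ultrametric trees, the difference is absorbed into the stationary
variance. `gls_fit` is a plain Cholesky-whitened GLS with the scale
profiled by maximum likelihood; its coefficients and likelihoods are
checked in the tests against brute-force matrix algebra and against
OLS when V = I.

Phylogenetic signal per gene comes as Pagel's λ̂ (ML over [0,1] of the
intercept-only GLS likelihood, with the boundary values checked
explicitly since the profile maximum can sit at 0 or 1) and Blomberg's
K (observed-to-expected ratio of mean squared deviations around the
phylogenetic mean; exactly 1 on equal-branch star trees and calibrated
to 1 in expectation under BM). Both are cross-checked against
`phytools::phylosig` in the test suite.

`hansen_fit_and_lrt` fits the multi-optimum OU model: branches are
painted with up to three regimes from a taxonomic grouping (a branch
takes its descendant tips' group when unanimous, else its parent's
regime; the root takes the outgroup-side regime), tip expectations are
regime-weight matrices `W(α)θ` with exponential-decay weights that sum
to one per tip, and α is optimized by bounded log-scale search over
[10⁻⁶, 50/T] with three restarts while θ and the scale are profiled by
GLS. The LRT against single-mean BM uses a nominal χ² with k degrees of
freedom (α plus k − 1 extra optima; the BM root mean and the first
optimum are exchangeable). The boundary effect on α (the BM limit sits
on the edge of the OU parameter space) makes the nominal χ² mildly
conservative-to-liberal depending on the regime; it is used as-is, as
is standard for this comparison. When the optimizer drives α to the
boundary and the OU likelihood falls numerically below BM, the fit is
reported at the BM limit with a note. How the two- and three-regime
partitions should be drawn is not determined by the method; the
packaged defaults split by subgenus (k = 2) and additionally by the
melanogaster species group (k = 3), exposed as configuration.

## The longevity signature (PGLS)

`run_signature` regresses each gene's standardized expression
(response) on the log-transformed, standardized trait (single predictor
plus intercept) under the four residual models, estimating λ and α
jointly with the coefficients by ML, and selects the best model by raw
maximum likelihood — not AIC — because the selection rule here is part
of the procedure being implemented; models differing by less than 10⁻⁶
in log-likelihood resolve to the simpler one. Slope p-values are
two-sided t-tests with n − 2 degrees of freedom, conditional on the
estimated covariance parameters (no correction for their estimation),
the common GLS practice. Benjamini–Hochberg q-values are attached, and
the hits at `p_threshold` (default .05) carry their correlation signs
into the concordance stage. The regression direction (expression as
response) follows from the residual models being defined on species
expression; trait-on-expression would imply a different error
structure. Excluding named species (e.g. a long-lived outlier) reruns
the analysis and reports the fraction of baseline hits that remain
significant.

## Direction concordance

`match_directions` counts, over the gene intersection, agreements
between signature signs and external direction calls (up/down for DE
tables; pro-/anti-longevity for curated effect tables).
`binomial_tail_p` is the exact one-sided upper tail at p = ½. The
sidedness is a derivation, not a convention choice: only the one-sided
upper tail on the same-direction count reproduces all eleven published
tally p-values shipped in `extdata` (including the below-half row, 94
of 200 matching, p ≈ 0.82 — a two-sided or lower-tail convention gives
≈ 0.21 there). `permutation_p` permutes the signature's sign labels
without replacement, recomputes the binomial tail each time, and uses
the (1 + hits)/(B + 1) estimator so no permutation p is exactly zero.
The percent-matching column rounds half away from zero, matching how
such tables are conventionally printed.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
pipeline assumes, plus ground-truth labels:

* **Tree**: pure-birth (Yule) rescaled to a fixed depth — the simplest
  ultrametric process; the packaged 14-taxon fixture has the
  two-subgenus structure and 56-My depth of the target clade.
* **Traits**: log lifespan under stationary OU around log(25 days)
  with the default α = 0.0673 and σ² = 0.142 per My — the
  divergence-plateau parameters of the real data, giving a stationary
  SD of about one log unit, i.e. roughly the observed several-fold
  lifespan range. Log mass follows the lifespan deviations with
  coefficient 0.5 plus its own OU noise, reproducing the positive
  mass–lifespan association.
* **Expression**: null genes are BM or stationary-OU draws on the tree
  (default mix 15/85), standardized. Signature genes (default 6% of
  genes, matching the rough hit fraction such studies report) are
  `sqrt(R²) · sign · z + sqrt(1 − R²) · η` with `z` the standardized
  log lifespan and `η` the same tree-structured noise as null genes,
  orthogonalized against `z` in-sample. The orthogonalization is a
  deliberate choice: it makes each signature gene's realized R² equal
  the target exactly, so power results are a property of the method
  rather than of residual sampling noise in a 14-species draw, while
  the residual keeps its phylogenetic covariance so PGLS assumptions
  still hold by construction.
* **Counts**: Poisson around `exp(logRPKM) · length/10³ · library/10⁶`
  (negative binomial behind an overdispersion knob). Poisson is the
  default because each species is a single library here; biological
  dispersion is already absorbed by the evolutionary model.
* **DE tables**: signature genes sampled without replacement, each
  direction agreeing with the gene's sign with probability `q`
  (default 0.63, the mid-range of published agreement rates).
* **Divergence profiles** (`simulate_divergence_profile`): gene vectors
  drawn directly from the stationary OU (or BM) covariance, emitted on
  the standardized scale *without* per-row renormalization. At the
  default parameters the stationary variance σ²/(2α) ≈ 1.055 is already
  near 1, and renormalizing each row by its finite-sample SD across 14
  correlated tips would shrink the apparent divergence scale and bias
  plateau refits; the tests that recover (α, σ²) depend on this.

All generators are pure functions of their inputs and a seed;
per-operation sub-seeds are derived deterministically from one root
seed so that regenerating any single component is reproducible.

What the generator does **not** emulate: tissue heterogeneity,
read-level artifacts, ortholog-calling errors, batch structure, or any
mechanistic link between expression and lifespan — signature genes are
correlated with the trait by construction, not by biology. Passing
recovery tests therefore demonstrates that the estimators are correct
and calibrated under their own assumptions, not that those assumptions
hold in any particular real data set.

## Numerical choices and degenerate inputs

* Covariance matrices are symmetrized and Cholesky-checked; failures
  (e.g. duplicated rows from zero-length branches) get a small diagonal
  jitter with a warning, and zero-length branches can be collapsed
  beforehand with `collapse_zero_branches`.
* Scalar searches (λ, α, plateau α) use `optimize` on bounded
  intervals — λ on [0, 1] with explicit endpoint evaluation, α on the
  log scale over [10⁻⁶, 50/T] (3 restarts) or [10⁻⁸, 200/max x]
  (5 restarts for the plateau) — so they cannot diverge; likelihood
  ties break toward the simpler model.
* Constant expression rows are dropped with a warning at
  standardization; constant species columns are an error in the
  distance computation (the Spearman correlation is undefined), named
  by species.
* Exact-fit inputs (noiseless plateau points, y = Xβ exactly) are
  recovered to optimizer precision; these are asserted in the tests.

## Problem sizes in the shipped tests

The test suite simulates at the scale the analysis targets where that
is cheap (6,510 genes × 14 species for plateau recovery, 91 divergence
points, 20 replicates) and at reduced but statistically adequate sizes
for the heavier calibration loops (200 replicates for λ recovery, 200
genes for the two-regime OU classification, 1,000 null genes for the
PGLS type-I check, 30 outer replicates at B = 150 for bootstrap
coverage). These sizes were chosen so each property has enough
Monte-Carlo resolution for its assertion; the assertions state the
tolerances.

## Known limitations

* The LRT for OU versus BM uses the nominal χ² despite the boundary on
  α; per-gene classification percentages should be read with that in
  mind.
* PGLS p-values do not propagate uncertainty in λ̂ or α̂; with 14
  species this conditioning is the dominant approximation.
* Best-model selection by raw likelihood favors the richer models in
  small samples; an information-criterion alternative is available via
  the per-model table returned by `fit_gene_all_models`.
* The divergence-plateau fit treats the 91 pairwise points as
  independent observations, as the least-squares procedure defines it;
  they are not (each species participates in 13 pairs), which is
  exactly why the bootstrap resamples genes and the jackknife removes
  species rather than pairs.
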