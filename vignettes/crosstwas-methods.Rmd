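---
title: "Cross-tissue TWAS with Cauchy combination and fine-mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue TWAS with Cauchy combination and fine-mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstwas)
```

# The analysis chain

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a gene's expression is associated with a trait. The
chain implemented here has five stages:

1. **Model training.** For each gene, SNPs within 1 Mb of the gene body are
   candidate predictors. Per-tissue weights $B = [\beta_1, \dots, \beta_d]$
   (SNPs × tissues) are estimated jointly across tissues by minimizing

   $$\sum_t \frac{1}{2N_t}\lVert y_t - X_t\beta_t\rVert_2^2
     + \lambda_1 \sum_{t}\sum_j |\beta_{jt}|
     + \lambda_2 \sum_j \lVert B_{j\cdot}\rVert_2,$$

   a sparse-group LASSO: the $\ell_1$ term drives within-tissue sparsity,
   the row-wise $\ell_2$ term borrows strength across tissues by selecting
   or dropping a SNP jointly for all tissues.

2. **Association.** With trained weights $w$, GWAS summary z-scores $z_l$,
   and a reference-panel SNP covariance $\Sigma$, the gene-level statistic
   is
   $$Z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} z_l, \qquad
     \sigma_g^2 = w^\top \Sigma w,$$
   which needs no individual-level GWAS data.

3. **Cross-tissue combination.** Per-gene tissue P values are transformed
   to standard Cauchy quantiles and averaged,
   $T = \tfrac1d\sum_i \tan\{(1/2 - p_i)\pi\}$; under the null $T$ is again
   standard Cauchy, so $p_{\text{comb}} = 1/2 - \arctan(T)/\pi$.

4. **Selection.** Bonferroni at $\alpha/m$ (strict `<`), with genes in
   LD-extensive regions (default: extended MHC, chr6:25–34 Mb) reported but
   removed from the final list.

5. **Fine-mapping.** Within regions of correlated predicted expression,
   causal-gene configurations $c$ are scored by
   $z \sim \mathcal N(0,\, S + v\, S_{\cdot c} S_{c \cdot})$ against
   $z \sim \mathcal N(0, S)$, where $S = \Omega + \text{ridge}\cdot I$ and
   $\Omega_{ij} = w_i^\top \Sigma w_j / (\sigma_i\sigma_j)$. Posteriors use
   a per-gene causal prior $p_0$; per-gene posterior inclusion
   probabilities (PIPs) and a 90% credible set are reported.

# Consistent-grid cross-validation

The distinctive training choice is how hyperparameters are tuned. A single
ordered list of $(\lambda_1, \lambda_2)$ pairs — a geometric ladder of 10
values per penalty from $\lambda_{\max} = \max_{j,t}|X_t^\top y_t|/N_t$
down to $10^{-3}\lambda_{\max}$, crossed into 100 pairs — is used in
*every* fold of a five-fold cross-validation, which makes tuning errors
comparable across folds. The pair with the lowest tuning error, averaged
over tissues and then folds, is selected; ties go to the larger
$(\lambda_1, \lambda_2)$ (the sparser model), exact duplicates to the
first occurrence.

Crucially, model performance — the Pearson correlation $r$ between
predicted and observed expression, with
$t = r\sqrt{(n-2)/(1-r^2)}$ giving a two-sided P — is computed **only from
out-of-fold predictions** pooled across folds. Evaluating a model on the
data that trained it inflates $r$: on pure-noise expression, a full-data
refit at a moderate penalty shows systematically higher in-sample $r$ than
the out-of-fold estimate (the package exposes `insample_performance()` so
the contrast can be reproduced; the test suite asserts it by a sign test
across 50 null genes, holding the penalty pair fixed at
$0.1\lambda_{\max}$ — under the consistent-grid CV itself, noise genes
correctly select maximal shrinkage, where both estimates are exactly zero
and the contrast would be uninformative). Out-of-fold evaluation keeps the
retention rule ($r \ge 0.1$ **and** $p < 0.05$; equivalently a retained
$r^2$ of at least $0.01$) meaningful.

The final weights are a full-data refit at the selected pair — the
selected pair is what cross-validation estimates; the refit uses all
samples for the weights while performance continues to be quoted from
held-out predictions only. Standardization statistics are always computed
on the training fold alone and applied to its validation fold, so no
leakage occurs. Fold assignment is stratified per tissue and fully seeded.

## Optimization

The objective is minimized by proximal gradient descent (ISTA) with the
sparse-group proximal map: coordinate soft-thresholding by $s\lambda_1$
followed by row-wise group shrinkage by $s\lambda_2$, with step size
$s = 1/\max_t \operatorname{eig}_{\max}(X_t^\top X_t/N_t)$. This step
choice makes the recorded objective trace non-increasing — asserted by
tests — and iteration stops at a relative objective change below $10^{-6}$
(default) or 5,000 iterations (a warning flag, not an error). Correctness
is certified three independent ways: KKT residuals below $10^{-4}$,
agreement with an ADMM solver written separately in the test suite
(objective within $10^{-6}$ on 100 random small instances), and agreement
with `glmnet` in the $\lambda_2 = 0$ single-tissue case, where the two
objectives coincide exactly. The $1/(2N_t)$ loss normalization equalizes
tissue contributions across unequal sample sizes and makes the $\lambda$
scales interpretable across tissues.

# What the synthetic generator emulates

The generator produces the three inputs the chain consumes, with recorded
ground truth.

**Genotypes.** Per gene, an independent cis block of SNPs; each of two
haplotypes per individual comes from a latent Gaussian AR(1) copula with
adjacent-SNP correlation `ld_rho`, thresholded at the MAF quantile; the
dosage is the haplotype sum. Blocks sit 4 Mb apart so 1 Mb cis windows
never cross blocks; a `shared_blocks` mode places two genes on one block
(with disjoint causal eQTL sets) to exercise fine-mapping disambiguation.

**Expression.** Each gene receives `n_causal_eqtl` causal SNPs whose
per-tissue effects share an exchangeable correlation `cross_tissue_cor`,
implemented as $\beta_t = \sqrt{\rho}\,u + \sqrt{1-\rho}\,e_t$ so that
$\rho = 1$ gives exactly identical effects. The genetic score is rescaled
to variance `h2_expr` (panel-wide) and unit-total noise added, so
heritability plus noise share is 1 by construction. Tissues use
overlapping donor subsets drawn without replacement, reproducing unequal
per-tissue sample sizes.

**GWAS.** Summary statistics are drawn directly at the summary level:
per block, $Z \sim \mathcal N(\sqrt{n}\,\gamma,\, R)$ with
$\gamma = R\,b_{\text{std}}$, $R$ the panel dosage correlation and
$b_{\text{std}}$ the standardized per-SNP trait effects induced by the
causal genes' effects through the across-tissue mean of the true eQTL
weights. This matches the summary-statistics contract of the association
stage and keeps the per-tissue statistics exactly $\mathcal N(0,1)$ under
the null. A slower individual-level mode draws a fresh cohort, builds the
quantitative trait from the genetic expression scores plus unit noise,
and computes marginal regression z-scores; it serves as the independent
oracle for the summary-level statistic (agreement within $\pm 0.05$ at a
cohort of 5,000).

## Default conditions

Defaults mirror the reference-panel geometry of a multi-tissue eQTL
resource: 838 genotyped donors; ten tissues with donor fractions
205/838, 147/838, 165/838, 129/838, 194/838, 202/838, 170/838, 114/838,
170/838, 237/838; a GWAS of 455,258 individuals; a 1 Mb cis window.
Values that geometry does not fix are set once to field-realistic values:
50 genes at desk scale, 30 SNPs per block, MAFs uniform on (0.05, 0.5),
`ld_rho = 0.5` (moderate local LD), 3 causal eQTLs per gene,
`h2_expr = 0.2` (a strongly cis-heritable gene), `cross_tissue_cor = 0.8`
(cis effects are largely shared across tissues), 10% causal genes, and
`gene_effect_sd = 0.02` on the log-odds-per-expression-unit scale, small
effects of the size only a biobank-scale GWAS detects.

What the generator does **not** emulate: realistic human LD maps (blocks
are AR(1), not recombination-map shaped), cross-gene LD outside the shared
block mode, raw read counts or their normalization, PEER-style latent
confounders, allele-frequency/effect-size coupling, and case-control
ascertainment. Passing recovery tests on this generator therefore
demonstrates correctness of the statistical machinery under its stated
assumptions, not performance on real cohorts.

# Numerical and convention choices

* **Cauchy quantiles.** $\tan\{(1/2-p)\pi\}$ is evaluated through the
  cotangent identity $\cot(\pi p)$, avoiding cancellation in $1/2 - p$;
  below $10^{-15}$ the first-order form $1/(\pi p)$ is exact to machine
  precision. The combined tail uses $\arctan(1/T)/\pi$ for $T > 1$, again
  to avoid cancellation; P values are clipped to $1 - 10^{-16}$ above and
  the result floored at $10^{-300}$.
* **Performance degeneracy.** A constant prediction vector has $r$ defined
  as 0 and $p = 1$ (such models can never be retained).
* **Harmonization.** GWAS z-scores are matched to model SNPs by id;
  swapped allele frames negate $z$; strand-ambiguous pairs (A/T, C/G) are
  dropped rather than frequency-resolved — conservative and deterministic.
* **Coordinates.** 1-based closed intervals everywhere (a SNP exactly at
  `tss - window` is cis) except the region blacklist, which is half-open
  `[start, end)`: a gene ending exactly at a region's start is not
  flagged.
* **Odds ratios.** Table-style OR columns are produced by the per-SD
  convention $\text{se}_g = 1/(\sigma_g\sqrt n)$,
  $\text{effect} = Z_g \cdot \text{se}_g$, CI $\pm 1.96\,\text{se}_g$,
  exponentiated. This is a labelled convention, not an identity: published
  TWAS OR columns rarely state their scale.
* **Fine-mapping priors.** $p_0 = 10^{-3}$ and $v = 40$ (the conventional
  defaults of TWAS fine-mapping), ridge 0.1 on $\Omega$ for invertibility
  (documented because it perturbs Bayes factors), enumeration of
  configurations up to `max_causal = 3` with the null model included in
  the normalization — so a credible set can be effectively empty when the
  null dominates. Regions are connected components of
  $|\Omega| > 0.05$ within a chromosome.
* **Credible sets.** Genes sorted by PIP (ties by id) accumulate
  normalized PIP mass until it reaches $\rho = 0.9$; the comparison is
  `>=`, so a gene whose cumulative share hits $\rho$ exactly closes the
  set.
* **Untestable genes.** $\sigma_g^2 < 10^{-8}$ (e.g. all model SNPs
  monomorphic in the panel) skips the gene with a logged reason rather
  than producing an unstable statistic.

# Problem sizes used by the checks

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is informative: the
convex-solver comparison on 100 instances of at most 10 SNPs × 3 tissues;
null calibration on 400 genes × 5 tissues (2,000 gene-tissue models);
summary-vs-individual agreement on 20 genes with a cohort of 5,000;
weight recovery on 50 genes at $h^2 = 0.5$ with a 2,000-donor panel;
fine-mapping recovery on 50 two-gene shared-block replicates; the
end-to-end run in `scripts/acceptance.R` at the default conditions above.

# Known limitations

* The Cauchy combination is exactly uniform under the null only when the
  per-tissue statistics are independent or perfectly dependent. Under the
  intermediate dependence that any multi-tissue analysis induces (one
  shared GWAS, correlated per-tissue predictions), its mid-range
  distribution deviates measurably — a Kolmogorov–Smirnov test against
  uniformity over a few hundred null genes detects it — while the tail,
  which drives discovery at Bonferroni-scale thresholds, remains accurate
  (type-I error at $\alpha = 0.05$ is nominal in the same simulations).
  This is a property of the combination method itself, visible in a
  package-free simulation of correlated normal statistics, and is the one
  calibration assertion the suite leaves failing by design.
* Enumeration-based fine-mapping is exponential in region size; regions
  beyond 25 genes require `max_causal` to cap the configuration count.
  No stochastic-search fallback is provided.
* The OR scale convention above is one defensible reading; effect sizes
  should be compared across studies only up to that convention.
* Model training assumes residualized, inverse-normal expression (the
  `preprocess_expression()` contract); raw counts are out of scope.
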