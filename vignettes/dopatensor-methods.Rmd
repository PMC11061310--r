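---
title: "Methods: sparse multi-tissue components and pathway-stratified polygenic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse multi-tissue components and pathway-stratified polygenic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopatensor)
```

# Overview

`dopatensor` implements an analysis chain for multi-tissue brain
transcriptomics: normalize per-tissue expression into a common
individuals x genes x tissues tensor, factorize that tensor into sparse
latent components, screen components against technical confounders,
diagnosis and polygenic risk, characterize component gene sets by
permutation enrichment, check their replication in an independent dataset,
and finally relate a component-restricted ("parsed") polygenic risk score
to neurochemical and functional brain phenotypes via per-cohort regression
and a Fisher-z fixed-effect meta-analysis.

The original data this style of analysis targets (post-mortem brain
RNA-seq, genotypes, dynamic PET) are access-restricted, so the package
ships a first-class synthetic-data module whose generators plant known
structure. Every stage is tested against that known structure.

# The tensor model and its estimation

## Model

Expression is modeled trilinearly:

$$Y_{ngt} \approx \sum_{c=1}^{K} A_{nc}\, B_{tc}\, X_{cg},$$

with an individual-score matrix $A$, a tissue-score matrix $B$, and a
gene-loading matrix $X$. Gene loadings carry a spike-and-slab prior: each
$X_{cg}$ is exactly zero with probability $1-\pi_c$ and drawn from a
Gaussian slab $N(0, v_c)$ otherwise, so each component learns its own
sparsity level $\pi_c$ and every gene gets a posterior inclusion
probability (PIP).

## Estimation

`fit_decomposition()` uses block coordinate ascent:

* $A$ and $B$ are updated by ridge-regularized least squares on the
  corresponding tensor unfoldings (ridge `1e-6`, used purely for numerical
  conditioning);
* $X$ is updated by a variational spike-and-slab regression of each gene's
  fiber on the Khatri-Rao design built from $A$ and $B$, with
  expectation-maximization updates of $\pi_c$, $v_c$ and the noise
  variance.

Scale indeterminacy is fixed after each iteration by rescaling $A$ columns
to unit standard deviation and $B$ columns to unit maximum absolute value,
pushing all scale into $X$. Sign indeterminacy is left in place and every
downstream consumer is sign-invariant (absolute correlations, sign
alignment before averaging).

Convergence is declared when the relative change of the residual sum of
squares falls below `tol = 1e-6`, with a 2000-iteration cap. The residual
decreases at every least-squares step; the shrinkage step can raise it by a
bounded amount (empirically below $10^{-3}$ of the initial residual per
iteration), which is why the trace test in the suite allows upticks at that
scale rather than demanding strict monotonicity.

Components whose PIPs all stay below `pip_floor = 0.1` are pruned. We
recommend starting with more components than you expect (`max_components`
well above the plausible rank); superfluous components shrink away. The
default of 100 suits discovery-scale tensors; the examples and tests use
6-10 components on small planted tensors.

## Multi-run clustering

The factorization is non-convex, so `fit_decomposition_runs()` repeats it
from independent random starts (10 runs in the reference configuration) and
`cluster_runs()` links components across runs whenever the absolute Pearson
correlation of their gene loadings reaches a threshold, takes connected
components of that graph as clusters, aligns signs to each cluster's first
member, and averages $A$, $B$, $X$ and the PIPs. Clusters found in at
least two distinct runs are retained as robust.

The default linkage threshold is 0.6. Single linkage can chain two distinct
components together through one occasional "mixed" local optimum that
correlates moderately with both; with only a handful of runs this chaining
risk is material, and the package's own recovery checks therefore cluster 3
runs at 0.7. With 10 runs the bridge component is outvoted in the combined
average and 0.6 is a reasonable default.

## Tissue activity and membership

`tissue_activity()` scales each component's tissue-score column by its
maximum absolute entry, so scaled scores live in $[-1, 1]$, and calls a
tissue active when $|{\rm scaled}| \ge 0.5$. We read "largest score 1,
lowest $-1$" as max-absolute scaling because it preserves zero and the sign
structure; a literal min-max affine scaling is available via
`method = "min_max"`. Component membership uses the median-probability
convention: genes with PIP $\ge 0.5$, ordered by absolute loading.

# Preprocessing

`prep_tensor()` applies, per tissue:

1. gene filters: mitochondrial genes out; genes with median expression
   below 0.1 out; genes whose median deviates more than 3 SD from the mean
   of per-gene medians out (a gene must pass in every tissue). The
   zero-fraction rule removes a gene only when more than 20% of its values
   are zero *in all tissues simultaneously*; we read the rule's "in all
   three tissues" conjunctively, and expose `zero_rule = "any"` for the
   disjunctive reading since the phrasing supports either.
2. sample outliers: the inter-array distance of a sample is one minus its
   mean Pearson correlation with all other samples; samples beyond
   mean + 3 SD are dropped. The distance metric is our choice — the
   procedure it implements only requires some inter-array distance.
3. normalization: $\log_2(x+1)$, then quantile normalization across
   samples (reference = mean of sorted columns; tied values are
   interpolated at their average ranks), then a per-gene Blom
   rank-inverse-normal transform
   $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$. A gene constant across
   samples maps to all-zero scores and is reported with a warning rather
   than silently kept.

Only individuals and genes present in all tissues enter the tensor.

# Component screening

* **Confounder filter.** Each component's scores are regressed jointly on
  all covariates; the component is removed when any *technical* covariate
  or genomic eigenvariate is significant below `p_threshold = 5e-4`.
  Diagnosis, age and sex never trigger removal. The threshold ties to a
  power argument: `correlation_power()` shows that a correlation of 0.274
  tested two-sided at $\alpha = 5\times10^{-4}$ in 238 individuals has 80%
  power (Fisher-z approximation), so the stringent threshold retains the
  sensitivity of the reference effect size.
* **Diagnosis ANCOVA.** F test of diagnosis adjusting for covariates;
  effect size is classical $\eta^2 = SS_{dx}/SS_{total}$ by default with
  partial $\eta^2$ behind a flag; Benjamini-Hochberg correction across
  components. The age filter is strict (`age > 17`).
* **PRS association.** One-tailed test in the diagnosis-consistent
  direction — an effect opposite to the diagnosis association is never
  called significant. Partial $R^2 = t^2/(t^2 + DF)$.
* **Named-gene regressions.** `gene_expression_association()` fits the
  full interaction structure (diagnosis x each expression term, diagnosis x
  age, plus covariates), or the controls-only structure when `dx_var =
  NULL`; transcript-level columns are handled identically.

# Enrichment machinery

`fisher_overrepresentation()` is the exact one-sided hypergeometric tail.
`empirical_enrichment()` draws uniform size-matched null sets and applies
the add-one rule $p = (1 + \#\{ \text{null} \ge \text{obs}\})/(1+B)$, so
10,000 permutations bound p below by $1/10001$ and the p-value never equals
zero. `matched_null_enrichment()` constrains each null set to match the
query's GC content, gene length and mean expression: universe genes are
binned by joint quantile bins (default 10 per covariate; quantile cuts
collapse automatically when a covariate is uninformative), each null set
draws the query's per-bin quota without replacement, and bins too small for
their quota are merged into the nearest bin by covariate centroid. The
binning resolution is our choice; the matching idea, not the bin count, is
the contract, and the matching-quality test asserts null sets sit within
one pooled SD of the query's covariate means. `mean_rank_geneset_test()`
is a competitive rank-sum test with a tie-corrected normal approximation;
all-tied scores return 0.5 (no information). `mean_rank_screen()` adjusts
over the full components x cell-types family.

# Replication across datasets

Two similarity measures: Jaccard index of membership sets, and absolute
Pearson correlation of loadings restricted to the shared gene universe
(both sign- and gene-order-invariant). `greedy_unique_pairing()` processes
discovery components in decreasing order of their best available
similarity, assigning each its argmax among unassigned replication
components — this guarantees unique pairs while approximating "each
discovery component takes its best match"; ties break deterministically by
column order. Permutation significance is scheme-explicit because
"permute the components" differs by measure: size-matched random gene sets
for Jaccard, gene-label permutation of the discovery loadings for
correlation.

# Polygenic scoring

QC retains common (MAF $\ge$ 1%), well-imputed (INFO $\ge$ 0.9) non-indel
SNPs outside the extended MHC (chr6:25-34 Mb, inclusive, on the summary's
own coordinates). Clumping iterates variants by ascending p and drops
variants within 250 kb of a kept variant at $r^2 > 0.1$ in the reference
dosages — the customary defaults of the scoring-software family, since no
specific values are mandated. Scores are weighted sums of effect-allele
dosages at the 10 canonical thresholds
$5\times10^{-8}, 10^{-6}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.2, 0.5, 1$;
dosages are aligned to the summary's effect allele first (flips resolved,
strand-ambiguous A/T and C/G variants dropped by default), making scores
invariant to the dosage file's allele coding. The parsed score restricts to
SNPs within 100 kb of the component's genes (boundaries inclusive, mapped
with `GenomicRanges`); the complementary score uses all remaining SNPs;
the two partition the clumped set at every threshold. Parsing subsets the
globally clumped SNP set rather than re-clumping within the subset,
matching the stated order of operations (map, match, score). Ancestry
assignment computes principal components on the merged target + reference
dosages, fits an L2-penalized logistic regression of reference labels on
the first 20 components (ridge penalty `1e-3`, small enough that
well-separated clusters get near-certain probabilities), and keeps targets
with predicted European-ancestry probability $\ge 0.9$.

# PET and ROI-level association

`patlak_ki()` implements the reference-region Patlak-Gjedde graphical
method: ordinary least squares of $C_{roi}(T)/C_{ref}(T)$ on
$\int_0^T C_{ref}\,dt \, / \, C_{ref}(T)$ over frames past `t_star`, slope
= $K_i$. The running integral is the trapezoid rule on frame mid-times
anchored at $(0,0)$; the synthetic TAC generator uses the same discrete
identity, so noiseless curves are recovered to machine precision — the
estimator is exactly unbiased on Patlak-form input. `t_star` defaults to
20 min, a conventional linear-phase start for the synthetic curves;
real tracers need their own choice.

`roi_association()` converts the PRS t-statistic to a correlation by
$r = \sqrt{t^2/(t^2+DF)}$ (the sign inherited from $t$, since the formula
yields a magnitude), Fisher-transforms it, and attaches
$se_z = 1/\sqrt{n-3}$ — the classic Fisher choice; `se_method =
"df_minus_1"` acknowledges covariate-consuming regressions instead.
`fixed_effect_meta()` pools with inverse-variance weights, a 99.5%
confidence interval by default, and a Bonferroni factor of 10
corresponding to the 10 PRS thresholds. The same machinery consumes
ROI-mean BOLD contrasts; voxel-wise inference is out of scope.

# The synthetic-data module

`simulate_tensor()` plants $K$ sparse components: individual scores are
standard normal (cases shifted by `dx_effect` on the diagnosis component),
tissue scores are binary activity patterns, and nonzero loadings have
random sign and magnitude uniform on $[1, 2]$ — continuous, tie-free, and
bounded away from zero so the default noise SD of 0.5 yields a
signal-to-noise ratio of at least 2. The signal is assembled on the
normalized scale, Gaussian noise added, and the result pushed through an
exp-link onto a positive RPKM-like scale with per-gene log-normal baselines
(SD 2 on the log2 scale): baseline heterogeneity is what makes the
median-based gene filters behave as they do on real RPKM data, and the
rank-based normalization removes it again. The default regime (200
individuals, 2000 genes, 3 tissues, 5 components, 5% sparsity) is the
package's reference recovery condition.

`simulate_genotypes_and_gwas()` uses a Gaussian-copula autoregressive
haplotype model: within an LD block, latent normals follow an AR(1) with
the requested correlation, are thresholded at the MAF quantile, and two
haplotypes sum to a dosage; blocks are independent. GWAS betas are
per-SNP marginal OLS estimates from a simulated external cohort, so the
summary weights carry realistic sampling noise. Causal SNPs concentrate
near a focal gene set at a requested fraction, and true betas are scaled
to the requested liability heritability. The defaults (5000 SNPs, blocks
of 10 at copula $r = 0.8$, 5000-individual GWAS, 50 causal SNPs, 30%
heritability) were chosen once as a realistic desk-scale regime.

What the generators do *not* emulate: read-level sequencing noise,
realistic haplotype panels and recombination maps, population structure in
expression, batch effects beyond the planted covariate contamination, and
PET image formation (curves only). Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical assumptions,
not robustness to everything real data can do.

# Numerical choices and degenerate inputs

* Empirical p-values always use the add-one rule; doubling permutations
  halves the attainable minimum.
* Ties: Blom and the mean-rank test use average ranks; quantile
  normalization interpolates at average ranks; greedy pairing breaks ties
  by column order; clumping orders by (p, chromosome, position).
* Constant inputs raise errors where they make the estimand undefined
  (constant PRS, all-zero tissue-score column, constant loading vector)
  and warnings where a sensible degenerate answer exists (constant gene
  after normalization, empty membership at threshold, empty QC output).
* A tensor that is entirely constant is rejected; individual zero-variance
  fibers are tolerated because exactly sparse zero-noise fixtures produce
  them legitimately.

# Problem sizes used by the test suite

The suite plants tensors of 100-200 individuals, 500-2000 genes and 3
tissues with 3-5 components, runs 2-3 decomposition restarts, and uses
1000 permutations with 200 replicates for the calibration checks; the
full-pipeline check runs 20 independent seeds with two 100-individual
imaging cohorts and a planted partial correlation of 0.3. These sizes were
chosen as the smallest regimes in which the statistical contracts are
cleanly identifiable.

# Known limitations

* The decomposition is a variational point-estimate scheme: PIPs are
  approximate posterior quantities and can be overconfident; the multi-run
  clustering is the practical safeguard.
* Single-linkage clustering can chain components (see above); inspect
  cluster sizes when runs are few.
* The confounder filter tests covariates jointly; strongly collinear
  covariate sets dilute per-term significance and aliased columns are
  dropped with a warning.
* LD clumping is greedy and reference-dependent; with very small reference
  panels, r-squared estimates are noisy.
* The Patlak estimator assumes irreversible uptake past `t_star`; no
  arterial-input models are provided.
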