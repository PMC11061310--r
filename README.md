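# dopatensor

Sparse multi-tissue tensor components and pathway-stratified polygenic
risk for dopaminergic phenotypes.

## What this package is for

Bulk brain RNA-seq sampled from several regions of the same individuals
can be arranged as a 3-D tensor (individuals x genes x tissues). Sparse
tensor decomposition extracts latent co-expression components from it —
each defined by an individual-score vector, a tissue-score vector, and a
sparse gene-loading vector — that capture gene networks shared across or
specific to brain regions. Components can then be screened against
technical confounders, tested for case-control differences and for
association with polygenic risk, characterized by gene-set enrichment with
covariate-matched permutation nulls, and replicated in an independent
dataset. Finally, a **parsed** polygenic risk score — restricted to SNPs
within 100 kb of one component's genes — can be related to in-vivo brain
phenotypes: dopamine synthesis capacity measured by the reference-region
Patlak–Gjedde influx constant Ki from dynamic PET, or ROI-level fMRI
contrasts, pooled across cohorts by Fisher-z fixed-effect meta-analysis.

The package is aimed at psychiatric-genomics and imaging-genetics analysts
who want this chain as tested, reusable R functions. Because the
motivating datasets are access-restricted, a synthetic-data module
generates every input with known planted structure: expression tensors
with sparse components, LD-block genotypes with matching GWAS summary
statistics, Patlak-consistent time-activity curves, and phenotypes with a
planted partial correlation.

## The model at the core

The expression tensor is factorized as

    Y[n,g,t] ≈ Σ_c A[n,c] · B[t,c] · X[c,g]

with a spike-and-slab prior on the gene loadings `X`: each loading is
exactly zero with probability 1 − π_c or drawn from a Gaussian slab,
giving every component its own sparsity level and every gene a posterior
inclusion probability. Estimation alternates ridge least squares for `A`
and `B` with a variational spike-and-slab update for `X`. The
factorization is repeated from independent random starts and components
are clustered across runs by loading correlation; clusters found in two or
more runs are combined by sign-aligned averaging.

Downstream statistics follow standard forms: ANCOVA F tests with
Benjamini–Hochberg correction, one-tailed direction-constrained PRS tests
with partial R² = t²/(t² + DF), one-sided Fisher/permutation enrichment
with add-one empirical p-values, Patlak slopes by OLS, and inverse-variance
pooling of Fisher-z correlations.

## Worked example

Simulate a 120-individual, 600-gene, 3-tissue dataset with three planted
components (one carrying a diagnosis effect), run the full chain, and pool
a planted PRS–phenotype effect of r = 0.3 across two imaging cohorts:

```r
library(dopatensor)
set.seed(1)

sim  <- simulate_tensor(tensor_sim_params(n_individuals = 120,
                                          n_genes = 600,
                                          n_components = 3, seed = 42))
tens <- prep_tensor(sim$tissue_mats)
fits <- fit_decomposition_runs(tens, n_runs = 2, max_components = 8,
                               seed = 7,
                               hyperparams = list(max_iter = 250))
cl   <- cluster_runs(fits, abs_corr_threshold = 0.7)

md  <- sim$metadata[match(rownames(cl$A), sim$metadata$individual), ]
scr <- diagnosis_ancova(cl$A, md, covariates = c("age", "sex"))
scr
#> # A tibble: 3 × 8
#>   component       F   df1   df2       p      eta2 dx_sign   p_fdr
#> 1 K1        0.0112      1   107 0.916   0.0000989       1 0.938
#> 2 K2        9.72        1   107 0.00235 0.0809         -1 0.00704
#> 3 K3        0.00613     1   107 0.938   0.0000560       1 0.938
```

`K2` is the diagnosis-associated component (F[1,107] = 9.7, classical
η² = 0.08, FDR-significant); its 31-gene membership and caudate-only
activity follow from the inclusion probabilities and scaled tissue scores:

```r
k   <- scr$component[which.min(scr$p)]
mem <- cluster_memberships(cl)[[k]]
dplyr::filter(tissue_activity(cl$B), component == k)
#>   tissue component scaled_score active
#> 1 CN     K2             -1      TRUE
#> 2 DLPFC  K2              0.0235 FALSE
#> 3 HP     K2              0.0188 FALSE
```

Parse polygenic risk for that component's genes and pool the association
with a simulated phenotype across two cohorts:

```r
ann   <- simulate_annotation(attr(tens, "gene_ids"), seed = 2)
gsim  <- simulate_genotypes_and_gwas(
  geno_sim_params(n_snps = 800, n_gwas = 2000, n_target = 200, seed = 3),
  ann, mem)
clump <- ld_clump(snp_qc(gsim$gwas), gsim$dosages)
prs   <- parse_prs(gsim$dosages, clump, mem, ann,
                   dosage_info = gsim$dosage_info)
# parsed + complementary SNP counts partition the clumped set at each of
# the 10 GWAS p-value thresholds (5e-8 ... 1), e.g. 37 + 300 at p <= 1

pv      <- dplyr::filter(prs, flavor == "parsed", threshold == 1)
pvec    <- setNames(pv$score, pv$individual)
cohorts <- dplyr::bind_rows(lapply(1:2, function(i) {
  idx  <- seq((i - 1) * 100 + 1, i * 100)
  covs <- data.frame(age = runif(100, 20, 60))
  ph   <- simulate_imaging_phenotype(pvec[idx], 0.3, covs, seed = 10 + i)
  roi_association(cbind(ph, prs = pvec[idx], covs),
                  "phenotype", "prs", "age", cohort = paste0("cohort", i))
}))
fixed_effect_meta(cohorts, m_tests = 10)
#> # A tibble: 1 × 9
#>   pooled_z ci_lo ci_hi           p p_bonferroni    r2
#> 1    0.382 0.180 0.583 0.000000106   0.00000106 0.133
```

The pooled Fisher-z of 0.38 (99.5% CI [0.18, 0.58]) recovers the planted
effect: `tanh(0.382)² = 0.13` of phenotype variance, Bonferroni-corrected
over the 10 PRS thresholds.

Result objects are tibbles throughout; fitted objects support
`tidy()`, `glance()` and `autoplot()` (tissue-activity heatmaps, forest
plots, Patlak diagnostic plots via `plot_patlak()`).

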