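#' Simulation parameters for the multi-tissue expression tensor
#'
#' Bundles the knobs of the synthetic expression generator. Defaults define
#' the reference simulation regime used throughout the package's tests: 200
#' individuals, 2000 genes, 3 tissues, 5 planted sparse components at 5%
#' gene support, and additive Gaussian noise giving a signal-to-noise ratio
#' of about 3 on supported entries.
#'
#' @param n_individuals,n_genes,n_tissues,n_components Tensor dimensions and
#'   number of planted components.
#' @param sparsity Fraction of genes with nonzero loading per component.
#' @param tissue_pattern Binary matrix (`n_tissues` x `n_components`) of
#'   tissue activity per component; `NULL` cycles through single-tissue,
#'   pairwise and all-tissue patterns.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   normalized scale.
#' @param dx_component Index of the component carrying a diagnosis effect.
#' @param dx_effect Standardized mean shift of cases on that component's
#'   individual scores.
#' @param case_fraction Fraction of individuals labelled cases.
#' @param contaminate_component Optional component index whose individual
#'   scores are rebuilt as 0.8 x scaled RIN plus noise, to exercise the
#'   confounder filter. `NA` disables contamination.
#' @param rpkm_log_offset Mean per-gene baseline added on the log2 scale
#'   before the exp-link back to the positive RPKM-like scale.
#' @param gene_baseline_sd Standard deviation of per-gene log2 baselines,
#'   giving genes realistically heterogeneous expression levels (removed by
#'   the rank-based normalization downstream).
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @return A list of class `tensor_sim_params`.
#' @export
tensor_sim_params <- function(n_individuals = 200, n_genes = 2000,
                              n_tissues = 3, n_components = 5,
                              sparsity = 0.05, tissue_pattern = NULL,
                              noise_sd = 0.5, dx_component = 1,
                              dx_effect = 0.8, case_fraction = 0.5,
                              contaminate_component = NA_integer_,
                              rpkm_log_offset = 5, gene_baseline_sd = 2,
                              seed = 1L) {
  stopifnot(n_individuals > 0, n_genes > 0, n_tissues > 0, n_components > 0,
            sparsity > 0, sparsity <= 1, noise_sd >= 0,
            dx_component >= 1, dx_component <= n_components,
            case_fraction >= 0, case_fraction <= 1)
  if (is.null(tissue_pattern)) {
    tissue_pattern <- default_tissue_pattern(n_tissues, n_components)
  }
  tissue_pattern <- as.matrix(tissue_pattern)
  stopifnot(nrow(tissue_pattern) == n_tissues,
            ncol(tissue_pattern) == n_components,
            all(tissue_pattern %in% c(0, 1)),
            all(colSums(tissue_pattern) >= 1))
  structure(list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues), n_components = as.integer(n_components),
    sparsity = sparsity, tissue_pattern = tissue_pattern,
    noise_sd = noise_sd, dx_component = as.integer(dx_component),
    dx_effect = dx_effect, case_fraction = case_fraction,
    contaminate_component = contaminate_component,
    rpkm_log_offset = rpkm_log_offset, gene_baseline_sd = gene_baseline_sd,
    seed = as.integer(seed)
  ), class = "tensor_sim_params")
}

default_tissue_pattern <- function(n_tissues, n_components) {
  # single tissues first, then pairs, then all-active; cycle if K is large
  pats <- list()
  for (t in seq_len(n_tissues)) {
    v <- numeric(n_tissues); v[t] <- 1; pats[[length(pats) + 1]] <- v
  }
  if (n_tissues >= 2) {
    for (t in seq_len(n_tissues - 1)) {
      v <- numeric(n_tissues); v[c(t, t + 1)] <- 1
      pats[[length(pats) + 1]] <- v
    }
  }
  pats[[length(pats) + 1]] <- rep(1, n_tissues)
  idx <- rep(seq_along(pats), length.out = n_components)
  matrix(unlist(pats[idx]), nrow = n_tissues)
}

#' Simulate a multi-tissue expression tensor with planted sparse components
#'
#' Draws individual scores, binary tissue scores and sparse gene loadings,
#' forms the trilinear signal `sum_c A[n,c] B[t,c] X[c,g]`, adds Gaussian
#' noise on the normalized scale, and maps the result through an exp-link to
#' an RPKM-like positive scale, so the preprocessing pipeline
#' (log2, quantile, Blom) has real work to do. Cases receive a standardized
#' shift of `dx_effect` on component `dx_component`'s individual scores.
#' Sample covariates (age, sex, RIN, mapping rates, genomic eigenvariates)
#' are generated independent of the planted scores unless
#' `contaminate_component` is set.
#'
#' @param params A [tensor_sim_params()] object.
#' @return A list with elements `tissue_mats` (named list of genes x samples
#'   raw positive matrices), `truth` (planted `individual_scores`,
#'   `tissue_scores`, `gene_loadings`, `membership`, plus the noiseless
#'   `signal` array and realized normalized-scale array `z`), and `metadata`
#'   (a tibble of per-individual covariates).
#' @export
simulate_tensor <- function(params) {
  stopifnot(inherits(params, "tensor_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_individuals; g <- p$n_genes; tt <- p$n_tissues; k <- p$n_components

  ind_ids <- sprintf("ind%03d", seq_len(n))
  gene_ids <- sprintf("gene%05d", seq_len(g))
  tissue_labels <- if (tt == 3) c("CN", "HP", "DLPFC") else
    sprintf("tissue%d", seq_len(tt))

  n_case <- round(p$case_fraction * n)
  diagnosis <- rep(c("SCZ", "NC"), c(n_case, n - n_case))

  A <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(ind_ids, sprintf("C%d", seq_len(k))))
  A[diagnosis == "SCZ", p$dx_component] <-
    A[diagnosis == "SCZ", p$dx_component] + p$dx_effect
  B <- p$tissue_pattern
  dimnames(B) <- list(tissue_labels, colnames(A))

  support_size <- max(1L, round(p$sparsity * g))
  X <- matrix(0, k, g, dimnames = list(colnames(A), gene_ids))
  membership <- vector("list", k)
  names(membership) <- colnames(A)
  for (c in seq_len(k)) {
    supp <- sample.int(g, support_size)
    # continuous magnitudes bounded away from zero: no exact ties, SNR >= 2
    X[c, supp] <- sample(c(-1, 1), support_size, replace = TRUE) *
      stats::runif(support_size, 1, 2)
    membership[[c]] <- gene_ids[sort(supp)]
  }

  # metadata: covariates orthogonal to A by construction (independent draws)
  meta <- tibble::tibble(
    individual = ind_ids,
    diagnosis = factor(diagnosis, levels = c("NC", "SCZ")),
    age = round(stats::runif(n, 18, 80), 1),
    sex = factor(sample(c("M", "F"), n, replace = TRUE)),
    race = factor(sample(c("EUR", "AFR"), n, replace = TRUE, prob = c(.6, .4))),
    pmi = round(stats::runif(n, 5, 60), 1),
    total_assigned_gene = stats::runif(n, 0.3, 0.6),
    rrna_rate = stats::runif(n, 1e-5, 1e-3),
    mito_rate = stats::runif(n, 0.01, 0.2)
  )
  for (t in seq_len(tt)) {
    meta[[paste0("rin_", tolower(tissue_labels[t]))]] <-
      round(stats::runif(n, 6, 9.5), 1)
  }
  for (j in 1:10) meta[[paste0("ge", j)]] <- stats::rnorm(n, sd = 0.05)

  if (!is.na(p$contaminate_component)) {
    cc <- as.integer(p$contaminate_component)
    stopifnot(cc >= 1, cc <= k)
    rin <- meta[[paste0("rin_", tolower(tissue_labels[1]))]]
    A[, cc] <- 0.8 * as.numeric(scale(rin)) + sqrt(1 - 0.64) * stats::rnorm(n)
  }

  signal <- array(0, c(n, g, tt),
                  dimnames = list(ind_ids, gene_ids, tissue_labels))
  for (t in seq_len(tt)) {
    signal[, , t] <- A %*% (B[t, ] * X)
  }
  z <- signal + array(stats::rnorm(n * g * tt, sd = p$noise_sd), c(n, g, tt))
  dimnames(z) <- dimnames(signal)

  baseline <- stats::rnorm(g, p$rpkm_log_offset, p$gene_baseline_sd)
  tissue_mats <- lapply(seq_len(tt), function(t) {
    # genes x samples on a positive RPKM-like scale with per-gene baselines
    raw <- t(2^(sweep(z[, , t], 2, baseline, `+`)))
    tissue_matrix(raw, tissue_labels[t])
  })
  names(tissue_mats) <- tissue_labels

  list(
    tissue_mats = tissue_mats,
    truth = list(individual_scores = A, tissue_scores = B, gene_loadings = X,
                 membership = membership, signal = signal, z = z),
    metadata = meta
  )
}

#' Synthetic gene annotation on a compact genome
#'
#' Lays genes end to end across chromosomes with fixed spacing, and draws
#' per-gene GC content, length and mean expression used by the
#' covariate-matched enrichment nulls. Coordinates are BED-like: 0-based,
#' half-open.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_chrom Number of chromosomes to spread genes over.
#' @param gene_length_range,spacing Gene length range (bp) and fixed
#'   intergenic spacing (bp).
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `gc`, `length`,
#'   `mean_expr`.
#' @export
simulate_annotation <- function(gene_ids, n_chrom = 10,
                                gene_length_range = c(2e3, 2e5),
                                spacing = 5e4, seed = 1L) {
  set.seed(seed)
  g <- length(gene_ids)
  chrom <- sort(rep_len(seq_len(n_chrom), g))
  len <- round(stats::runif(g, gene_length_range[1], gene_length_range[2]))
  start <- integer(g)
  pos <- stats::setNames(rep(0, n_chrom), seq_len(n_chrom))
  for (i in seq_len(g)) {
    start[i] <- pos[chrom[i]]
    pos[chrom[i]] <- pos[chrom[i]] + len[i] + spacing
  }
  tibble::tibble(
    chrom = chrom, start = start, end = start + len, gene_id = gene_ids,
    gc = stats::runif(g, 0.3, 0.7), length = len,
    mean_expr = stats::rexp(g, rate = 0.2)
  )
}

#' Simulation parameters for genotypes and GWAS summary statistics
#'
#' Defaults give 5000 SNPs in LD blocks of 10 with adjacent-SNP copula
#' correlation 0.8, a 5000-individual external GWAS cohort, 50 causal SNPs
#' of which half sit within 100 kb of the focal gene set, and 30% liability
#' heritability.
#'
#' @param n_snps,block_size,within_block_r LD structure: SNPs per block and
#'   target adjacent-SNP latent (copula) correlation within a block;
#'   independence across blocks.
#' @param maf_range Interval for minor-allele frequencies, within (0, 0.5].
#' @param n_gwas External cohort size used to estimate marginal betas.
#' @param n_target Number of target individuals receiving dosages.
#' @param n_causal Number of causal SNPs.
#' @param causal_fraction_near_component Fraction of causal SNPs placed
#'   within 100 kb of the focal component's genes.
#' @param h2_liability Phenotypic variance explained by the causal SNPs.
#' @param flank Window (bp) defining "near" a focal gene.
#' @param seed Integer seed.
#' @return A list of class `geno_sim_params`.
#' @export
geno_sim_params <- function(n_snps = 5000, block_size = 10,
                            within_block_r = 0.8, maf_range = c(0.05, 0.5),
                            n_gwas = 5000, n_target = 200, n_causal = 50,
                            causal_fraction_near_component = 0.5,
                            h2_liability = 0.3, flank = 1e5, seed = 1L) {
  stopifnot(within_block_r >= 0, within_block_r < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            h2_liability >= 0, h2_liability < 1,
            causal_fraction_near_component >= 0,
            causal_fraction_near_component <= 1,
            n_causal <= n_snps)
  structure(list(
    n_snps = as.integer(n_snps), block_size = as.integer(block_size),
    within_block_r = within_block_r, maf_range = maf_range,
    n_gwas = as.integer(n_gwas), n_target = as.integer(n_target),
    n_causal = as.integer(n_causal),
    causal_fraction_near_component = causal_fraction_near_component,
    h2_liability = h2_liability, flank = flank, seed = as.integer(seed)
  ), class = "geno_sim_params")
}

# dosages from a Gaussian-copula AR(1) haplotype model; blocks independent
simulate_dosages <- function(n_ind, maf, block, within_block_r) {
  m <- length(maf)
  draw_haplo <- function() {
    zz <- matrix(stats::rnorm(n_ind * m), n_ind, m)
    if (within_block_r > 0) {
      for (j in 2:m) {
        if (block[j] == block[j - 1]) {
          zz[, j] <- within_block_r * zz[, j - 1] +
            sqrt(1 - within_block_r^2) * zz[, j]
        }
      }
    }
    sweep(zz, 2, stats::qnorm(maf), `<`) * 1
  }
  draw_haplo() + draw_haplo()
}

#' Simulate genotypes and matching GWAS summary statistics
#'
#' Generates dosages for an external GWAS cohort and for the target
#' individuals under a shared Gaussian-copula autoregressive LD-block model,
#' plants causal SNPs with the requested concentration near the focal gene
#' set, simulates a continuous liability phenotype in the external cohort,
#' and estimates per-SNP marginal ordinary-least-squares betas and p-values,
#' so sampling noise in the summary weights is realistic.
#'
#' @param params A [geno_sim_params()] object.
#' @param annotation Gene annotation tibble as from [simulate_annotation()].
#' @param focal_gene_set Character vector of focal gene ids (nonempty).
#' @return A list with `gwas` (summary tibble: snp_id, chrom, pos, a1, a2,
#'   beta, p, maf, info, is_indel), `dosages` (target individuals x SNPs
#'   matrix), `dosage_info` (counted/other allele per SNP), `liability`
#'   (true genetic liability of target individuals), and `causal` (tibble of
#'   causal SNPs with true betas).
#' @export
simulate_genotypes_and_gwas <- function(params, annotation, focal_gene_set) {
  stopifnot(inherits(params, "geno_sim_params"), length(focal_gene_set) > 0)
  p <- params
  set.seed(p$seed)

  # SNP positions uniform over the annotated genome
  chrom_span <- annotation |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$end) + p$flank, .groups = "drop")
  w <- chrom_span$span / sum(chrom_span$span)
  snp_chrom <- sample(chrom_span$chrom, p$n_snps, replace = TRUE, prob = w)
  snp_pos <- integer(p$n_snps)
  for (ch in chrom_span$chrom) {
    idx <- which(snp_chrom == ch)
    snp_pos[idx] <- sort(sample.int(chrom_span$span[chrom_span$chrom == ch],
                                    length(idx)))
  }
  ord <- order(snp_chrom, snp_pos)
  snp_chrom <- snp_chrom[ord]; snp_pos <- snp_pos[ord]
  snp_id <- sprintf("rs%06d", seq_len(p$n_snps))
  block <- paste(snp_chrom, (seq_len(p$n_snps) - 1) %/% p$block_size)
  maf <- stats::runif(p$n_snps, p$maf_range[1], p$maf_range[2])
  # unambiguous allele pairs only, so strand filtering never drops variants
  pair <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                 byrow = TRUE)[sample.int(4, p$n_snps, replace = TRUE), ,
                               drop = FALSE]

  focal <- annotation[annotation$gene_id %in% focal_gene_set, , drop = FALSE]
  near <- rep(FALSE, p$n_snps)
  for (i in seq_len(nrow(focal))) {
    near <- near | (snp_chrom == focal$chrom[i] &
                      snp_pos >= focal$start[i] + 1 - p$flank &
                      snp_pos <= focal$end[i] + p$flank)
  }
  if (!any(near)) {
    stop("no SNPs fall within ", p$flank, " bp of the focal gene set")
  }
  n_near <- min(round(p$causal_fraction_near_component * p$n_causal),
                sum(near))
  n_far <- min(p$n_causal - n_near, sum(!near))
  causal_idx <- c(sample(which(near), n_near),
                  if (n_far > 0) sample(which(!near), n_far))
  beta_true <- numeric(p$n_snps)
  beta_true[causal_idx] <- stats::rnorm(length(causal_idx))

  G_gwas <- simulate_dosages(p$n_gwas, maf, block, p$within_block_r)
  G_target <- simulate_dosages(p$n_target, maf, block, p$within_block_r)
  colnames(G_gwas) <- colnames(G_target) <- snp_id
  rownames(G_target) <- sprintf("ind%03d", seq_len(p$n_target))

  liab_gwas <- drop(G_gwas[, causal_idx, drop = FALSE] %*%
                      beta_true[causal_idx])
  if (p$h2_liability > 0 && stats::var(liab_gwas) > 0) {
    sc <- sqrt(p$h2_liability / stats::var(liab_gwas))
    beta_true <- beta_true * sc
    liab_gwas <- liab_gwas * sc
  } else {
    beta_true[] <- 0
    liab_gwas[] <- 0
  }
  y <- liab_gwas + stats::rnorm(p$n_gwas, sd = sqrt(1 - p$h2_liability))

  # marginal OLS per SNP, vectorized
  xc <- scale(G_gwas, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  beta_hat <- drop(crossprod(xc, yc)) / sxx
  df <- p$n_gwas - 2
  rss <- sum(yc^2) - beta_hat^2 * sxx
  se <- sqrt(rss / df / sxx)
  tstat <- beta_hat / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  maf_emp <- pmin(colMeans(G_gwas) / 2, 1 - colMeans(G_gwas) / 2)
  info_sim <- stats::runif(p$n_snps, 0.95, 1)
  gwas <- tibble::tibble(
    snp_id = snp_id, chrom = snp_chrom, pos = snp_pos,
    a1 = pair[, 1], a2 = pair[, 2],
    beta = beta_hat, p = pval,
    maf = maf_emp, info = info_sim, is_indel = FALSE
  )
  liability <- drop(G_target[, causal_idx, drop = FALSE] %*%
                      beta_true[causal_idx])
  list(
    gwas = gwas, dosages = G_target,
    dosage_info = tibble::tibble(snp_id = snp_id, counted_allele = pair[, 1],
                                 other_allele = pair[, 2]),
    liability = stats::setNames(liability, rownames(G_target)),
    causal = tibble::tibble(snp_id = snp_id[causal_idx],
                            beta_true = beta_true[causal_idx],
                            near_focal = near[causal_idx])
  )
}

#' Default PET frame timing
#'
#' A conventional dynamic FDOPA acquisition: 26 frames over ~94.5 minutes
#' with durations increasing from 30 s to 5 min.
#'
#' @return Tibble with `frame_start_min`, `frame_end_min`, `frame_mid_min`,
#'   `frame_dur_min`.
#' @export
tac_frames <- function() {
  dur <- c(rep(0.5, 4), rep(1, 3), rep(2, 5), rep(3.5, 4), rep(5, 10)) # min
  end <- cumsum(dur)
  tibble::tibble(frame_start_min = end - dur, frame_end_min = end,
                 frame_mid_min = end - dur / 2, frame_dur_min = dur)
}

# cumulative trapezoid of y over t, anchored at (0, 0)
cum_trapz0 <- function(t, y) {
  tt <- c(0, t); yy <- c(0, y)
  cumsum(c(0, diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2))[-1]
}

#' Simulate reference-region time-activity curves with known Ki
#'
#' Builds a gamma-variate reference curve and a target-region curve that
#' satisfies the discrete Patlak identity
#' `C_roi(T) = ki * int_0^T C_ref dt + vb * C_ref(T)` exactly on the frame
#' mid-time grid (trapezoid integral anchored at zero), then applies
#' multiplicative Gaussian noise with the stated coefficient of variation.
#'
#' @param ki Influx rate constant (per minute), >= 0.
#' @param vb Distribution-volume (intercept) term.
#' @param frames Frame table as from [tac_frames()].
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Integer seed.
#' @return Tibble: frame timing columns plus `roi_activity`, `ref_activity`.
#' @export
simulate_tac <- function(ki, vb, frames = tac_frames(), noise_cv = 0,
                         seed = 1L) {
  stopifnot(ki >= 0, vb >= 0, noise_cv >= 0,
            all(diff(frames$frame_mid_min) > 0))
  set.seed(seed)
  tm <- frames$frame_mid_min
  ref <- 100 * (tm / 10)^1.5 * exp(-tm / 25)  # gamma-variate input shape
  roi <- ki * cum_trapz0(tm, ref) + vb * ref
  if (noise_cv > 0) {
    roi <- roi * (1 + noise_cv * stats::rnorm(length(roi)))
    ref <- ref * (1 + noise_cv * stats::rnorm(length(ref)))
  }
  dplyr::bind_cols(frames, tibble::tibble(roi_activity = roi,
                                          ref_activity = ref))
}

#' Simulate an imaging phenotype with a planted partial correlation
#'
#' Residualizes the PRS on the covariates, standardizes the residual, and
#' constructs a phenotype whose population partial correlation with the PRS
#' (given the covariates) equals `effect_r` by construction. Covariates also
#' receive their own additive effects so adjustment matters.
#'
#' @param prs Numeric PRS vector (non-constant).
#' @param effect_r Target partial correlation, |effect_r| < 1.
#' @param covariates Data frame of numeric covariates (same rows as `prs`).
#' @param seed Integer seed.
#' @return Tibble with `individual`, `phenotype`.
#' @export
simulate_imaging_phenotype <- function(prs, effect_r, covariates = NULL,
                                       seed = 1L) {
  stopifnot(abs(effect_r) < 1)
  if (stats::sd(prs) == 0) stop("constant PRS vector")
  set.seed(seed)
  n <- length(prs)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    u <- as.numeric(scale(prs))
    cov_part <- 0
  } else {
    cv <- as.data.frame(covariates)
    num <- as.matrix(stats::model.matrix(~ ., cv)[, -1, drop = FALSE])
    u <- as.numeric(scale(stats::resid(stats::lm(prs ~ num))))
    cov_part <- drop(scale(num) %*% stats::rnorm(ncol(num), sd = 0.3))
  }
  pheno <- effect_r * u + sqrt(1 - effect_r^2) * stats::rnorm(n) + cov_part
  ids <- names(prs)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  tibble::tibble(individual = ids, phenotype = pheno)
}
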