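#' GWAS summary-statistic quality control
#'
#' Retains common (`maf >= maf_min`), well-imputed (`info >= info_min`),
#' non-indel variants outside the extended MHC region
#' (chr6:25-34 Mb by default, on the summary's own coordinates).
#'
#' @param summary GWAS summary tibble with columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `beta`, `p`, `maf`, `info`, `is_indel`.
#' @param maf_min,info_min QC cutoffs.
#' @param mhc Length-3 numeric: chromosome, window start, window end (bp,
#'   inclusive).
#' @return Filtered summary tibble (possibly empty, with a warning).
#' @export
snp_qc <- function(summary, maf_min = 0.01, info_min = 0.9,
                   mhc = c(6, 25e6, 34e6)) {
  out <- summary |>
    dplyr::filter(.data$maf >= maf_min,
                  .data$info >= info_min,
                  !.data$is_indel,
                  !(.data$chrom == mhc[1] & .data$pos >= mhc[2] &
                      .data$pos <= mhc[3]))
  if (nrow(out) == 0) warning("no variants survive QC")
  out
}

#' Map SNPs to gene windows
#'
#' A variant is selected when its position lies within `flank` bp of any
#' gene in the set (inclusive boundaries): on the same chromosome and with
#' `pos` in `[gene_start - flank, gene_end + flank]`, where gene
#' coordinates come from a BED-like annotation (0-based half-open, so the
#' 1-based gene span is `start + 1 .. end`).
#'
#' @param variants Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param annotation BED-like tibble: `chrom`, `start`, `end`, `gene_id`.
#' @param gene_set Character vector of gene ids; unannotated ids are
#'   reported and skipped.
#' @param flank Window size in bp (default 100000).
#' @return Character vector of selected `snp_id`s.
#' @export
map_snps_to_gene_windows <- function(variants, annotation, gene_set,
                                     flank = 1e5) {
  missing <- setdiff(gene_set, annotation$gene_id)
  if (length(missing)) {
    warning("unannotated gene ids skipped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  genes <- annotation[annotation$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(genes) == 0) return(character(0))
  win <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = pmax(genes$start + 1 - flank, 1),
                              end = genes$end + flank))
  vr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1))
  hits <- GenomicRanges::findOverlaps(vr, win)
  unique(variants$snp_id[S4Vectors::queryHits(hits)])
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Iterates variants by ascending association p-value; a variant is
#' retained unless it lies within `window_kb` of an already-retained
#' variant on the same chromosome with squared dosage correlation above
#' `r2_threshold` in the reference panel.
#'
#' @param summary QC'd GWAS summary tibble.
#' @param ref_dosages Reference dosage matrix (individuals x variants,
#'   column names = snp ids) covering all summary variants.
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.1 and
#'   250 kb).
#' @return Summary tibble restricted to index variants.
#' @export
ld_clump <- function(summary, ref_dosages, r2_threshold = 0.1,
                     window_kb = 250) {
  if (!all(summary$snp_id %in% colnames(ref_dosages))) {
    stop("variants missing from the LD reference")
  }
  ord <- order(summary$p, summary$chrom, summary$pos)
  kept <- integer(0)
  win <- window_kb * 1000
  for (i in ord) {
    near <- kept[summary$chrom[kept] == summary$chrom[i] &
                   abs(summary$pos[kept] - summary$pos[i]) <= win]
    ok <- TRUE
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(ref_dosages[, summary$snp_id[i]],
                   ref_dosages[, summary$snp_id[near], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      ok <- all(r2 <= r2_threshold)
    }
    if (ok) kept <- c(kept, i)
  }
  summary[sort(kept), , drop = FALSE]
}

default_prs_thresholds <- function() {
  c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5, 1)
}

# align dosages to the summary's effect allele; returns the aligned
# dosage matrix restricted to usable variants plus their summary rows
align_dosages <- function(dosages, summary, dosage_info,
                          drop_ambiguous = TRUE) {
  snp <- intersect(summary$snp_id, colnames(dosages))
  sm <- summary[match(snp, summary$snp_id), , drop = FALSE]
  d <- dosages[, snp, drop = FALSE]
  if (is.null(dosage_info)) {
    return(list(dosages = d, summary = sm))
  }
  di <- dosage_info[match(snp, dosage_info$snp_id), , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- sm$a1 == comp[sm$a2]
  if (drop_ambiguous && any(ambiguous)) {
    warning(sum(ambiguous), " strand-ambiguous variant(s) dropped")
  }
  same <- di$counted_allele == sm$a1 & di$other_allele == sm$a2
  flipped <- di$counted_allele == sm$a2 & di$other_allele == sm$a1
  usable <- (same | flipped) & !(drop_ambiguous & ambiguous)
  if (any(!(same | flipped))) {
    warning(sum(!(same | flipped)), " variant(s) with unresolvable allele ",
            "mismatch dropped")
  }
  d <- d[, usable, drop = FALSE]
  sm <- sm[usable, , drop = FALSE]
  fl <- flipped[usable]
  d[, fl] <- 2 - d[, fl]
  list(dosages = d, summary = sm)
}

#' Thresholded polygenic risk scores
#'
#' For each GWAS p-value threshold, scores each individual as the weighted
#' sum of effect-allele dosages over variants with `p <= threshold`
#' (per-SNP average via `average = TRUE`). Dosages are aligned to the
#' summary's effect allele first (flipped where the counted allele is the
#' other allele; strand-ambiguous A/T and C/G variants dropped by default),
#' making scores invariant to the dosage file's allele coding.
#'
#' @param dosages Individuals x variants dosage matrix in `[0, 2]`.
#' @param summary Clumped GWAS summary tibble.
#' @param thresholds Numeric vector of p-value thresholds (default: the
#'   standard 10-threshold ladder 5e-8 ... 1).
#' @param dosage_info Optional tibble `snp_id`, `counted_allele`,
#'   `other_allele` describing the dosage coding; `NULL` assumes dosages
#'   already count the effect allele.
#' @param flavor Label stored in the output (`"full"`, `"parsed"`,
#'   `"complementary"`).
#' @param average Per-SNP average instead of the weighted-sum convention.
#' @param drop_ambiguous Drop strand-ambiguous variants (default TRUE).
#' @return Long tibble: individual, threshold, score, n_snps, flavor.
#' @export
compute_prs <- function(dosages, summary,
                        thresholds = default_prs_thresholds(),
                        dosage_info = NULL, flavor = "full",
                        average = FALSE, drop_ambiguous = TRUE) {
  al <- align_dosages(dosages, summary, dosage_info, drop_ambiguous)
  ids <- rownames(al$dosages)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(al$dosages)))
  purrr::map_dfr(sort(thresholds), function(thr) {
    sel <- al$summary$p <= thr
    score <- if (any(sel)) {
      drop(al$dosages[, sel, drop = FALSE] %*% al$summary$beta[sel])
    } else {
      rep(0, length(ids))
    }
    if (average && sum(sel) > 0) score <- score / sum(sel)
    tibble::tibble(individual = ids, threshold = thr, score = score,
                   n_snps = sum(sel), flavor = flavor)
  })
}

#' Component-parsed and complementary polygenic risk scores
#'
#' Partitions the clumped variant set into SNPs within `flank` bp of the
#' component's genes (the parsed score) and all remaining SNPs (the
#' complementary score, a negative control), then computes both PRS
#' profiles. At every threshold the parsed and complementary SNP sets
#' partition the full set.
#'
#' @inheritParams compute_prs
#' @param component_genes Character vector of component gene ids.
#' @param annotation BED-like gene annotation.
#' @param flank Gene window in bp (default 100000).
#' @return Tibble with both flavors stacked (`flavor` column
#'   `"parsed"` / `"complementary"`).
#' @export
parse_prs <- function(dosages, summary, component_genes, annotation,
                      thresholds = default_prs_thresholds(),
                      dosage_info = NULL, flank = 1e5, average = FALSE,
                      drop_ambiguous = TRUE) {
  parsed_ids <- map_snps_to_gene_windows(summary, annotation,
                                         component_genes, flank)
  sm_parsed <- summary[summary$snp_id %in% parsed_ids, , drop = FALSE]
  sm_comp <- summary[!summary$snp_id %in% parsed_ids, , drop = FALSE]
  if (nrow(sm_parsed) == 0) warning("no SNPs map to the component genes")
  prs_p <- compute_prs(dosages, sm_parsed, thresholds, dosage_info,
                       flavor = "parsed", average = average,
                       drop_ambiguous = drop_ambiguous)
  prs_c <- compute_prs(dosages, sm_comp, thresholds, dosage_info,
                       flavor = "complementary", average = average,
                       drop_ambiguous = drop_ambiguous)
  dplyr::bind_rows(prs_p, prs_c)
}

#' Genotype-based ancestry assignment
#'
#' Computes principal components on the merged target + reference dosage
#' matrix, fits an L2-penalized (ridge) logistic regression of the
#' reference population labels on the first `n_pcs` components using
#' reference individuals only, and thresholds the predicted European
#' ancestry probability of the target individuals at `prob_threshold`.
#'
#' @param target_dosages,ref_dosages Dosage matrices over shared variants
#'   (individuals x variants).
#' @param ref_labels Binary vector for reference individuals (European = 1).
#' @param n_pcs Number of genetic eigenvariates used as predictors
#'   (default 20).
#' @param prob_threshold Keep threshold on the predicted probability
#'   (default 0.9).
#' @param lambda Ridge penalty for glmnet (default 1e-3; kept small so
#'   well-separated clusters receive near-certain probabilities).
#' @return Tibble: individual, prob_european, keep.
#' @export
ancestry_assignment <- function(target_dosages, ref_dosages, ref_labels,
                                n_pcs = 20, prob_threshold = 0.9,
                                lambda = 1e-3) {
  shared <- intersect(colnames(target_dosages), colnames(ref_dosages))
  stopifnot(length(shared) > n_pcs, length(ref_labels) == nrow(ref_dosages))
  merged <- rbind(ref_dosages[, shared, drop = FALSE],
                  target_dosages[, shared, drop = FALSE])
  keep_var <- apply(merged, 2, stats::sd) > 0
  merged <- scale(merged[, keep_var, drop = FALSE])
  sv <- svd(merged, nu = n_pcs, nv = 0)
  if (sum(sv$d > 1e-8) < n_pcs) {
    stop("fewer than ", n_pcs, " informative dimensions")
  }
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  idx_ref <- seq_len(nrow(ref_dosages))
  fit <- glmnet::glmnet(pcs[idx_ref, , drop = FALSE],
                        factor(ref_labels, levels = c(0, 1)),
                        family = "binomial", alpha = 0, lambda = lambda)
  prob <- as.numeric(stats::predict(fit,
                                    pcs[-idx_ref, , drop = FALSE],
                                    type = "response"))
  ids <- rownames(target_dosages)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(target_dosages)))
  tibble::tibble(individual = ids, prob_european = prob,
                 keep = prob >= prob_threshold)
}
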