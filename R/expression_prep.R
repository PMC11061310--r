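#' Construct a per-tissue expression matrix
#'
#' A thin wrapper validating a genes x samples nonnegative RPKM-scale
#' matrix and attaching a tissue label.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param tissue_label Single string naming the tissue.
#' @return The matrix with class `tissue_matrix` and a `tissue_label`
#'   attribute.
#' @export
tissue_matrix <- function(values, tissue_label) {
  values <- as.matrix(values)
  stopifnot(!anyNA(values), all(values >= 0),
            !is.null(rownames(values)), !is.null(colnames(values)),
            !anyDuplicated(rownames(values)))
  structure(values, tissue_label = tissue_label,
            class = c("tissue_matrix", class(values)))
}

#' Tissue label accessor
#' @param x A `tissue_matrix`.
#' @return The tissue label string.
#' @export
tissue_label <- function(x) attr(x, "tissue_label")

#' Filter genes across tissues before tensor assembly
#'
#' Removes mitochondrial genes, genes whose within-tissue RPKM median is
#' below `median_floor` or deviates more than `sd_mult` standard deviations
#' from the mean of per-gene medians in that tissue (a gene must pass in
#' every tissue), and genes whose zero fraction exceeds `zero_fraction`.
#' The zero-fraction rule is conjunctive by default: a gene is removed only
#' when its zero fraction exceeds the cutoff simultaneously in all tissues;
#' `zero_rule = "any"` gives the disjunctive reading.
#'
#' @param tissue_mats List of [tissue_matrix()] objects sharing a gene
#'   universe.
#' @param mito_gene_ids Character vector of mitochondrial gene ids.
#' @param median_floor,sd_mult,zero_fraction Filter parameters.
#' @param zero_rule `"all"` (default, conjunctive) or `"any"`.
#' @return Character vector of surviving gene ids (input order).
#' @export
filter_genes <- function(tissue_mats, mito_gene_ids = character(),
                         median_floor = 0.1, sd_mult = 3,
                         zero_fraction = 0.2,
                         zero_rule = c("all", "any")) {
  zero_rule <- match.arg(zero_rule)
  genes <- rownames(tissue_mats[[1]])
  for (m in tissue_mats) {
    stopifnot(setequal(rownames(m), genes))
  }
  keep <- !(genes %in% mito_gene_ids)
  zero_hits <- matrix(FALSE, length(genes), length(tissue_mats))
  for (i in seq_along(tissue_mats)) {
    m <- tissue_mats[[i]][genes, , drop = FALSE]
    med <- apply(m, 1, stats::median)
    keep <- keep & med >= median_floor
    keep <- keep & abs(med - mean(med)) <= sd_mult * stats::sd(med)
    zero_hits[, i] <- rowMeans(m == 0) > zero_fraction
  }
  zmask <- if (zero_rule == "all") {
    rowSums(zero_hits) == length(tissue_mats)
  } else {
    rowSums(zero_hits) > 0
  }
  keep <- keep & !zmask
  if (!any(keep)) stop("no genes survive the filters")
  genes[keep]
}

#' Flag outlier samples by inter-array distance
#'
#' The inter-array distance of a sample is one minus its mean Pearson
#' correlation with all other samples; a sample is flagged when its distance
#' exceeds the mean distance by more than `sd_mult` standard deviations.
#'
#' @param mat A [tissue_matrix()] (or plain genes x samples matrix) with at
#'   least 4 samples.
#' @param sd_mult Flagging multiplier.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(mat, sd_mult = 3) {
  if (ncol(mat) < 4) stop("need at least 4 samples")
  cc <- stats::cor(unclass(mat))
  d <- 1 - (rowSums(cc) - 1) / (ncol(mat) - 1)
  s <- stats::sd(d)
  flagged <- d > mean(d) + sd_mult * s
  colnames(mat)[flagged]
}

# per-column quantile normalization to the mean of sorted columns;
# ties within a column receive the mean of their target quantiles
quantile_normalize <- function(m) {
  if (nrow(m) == 1) return(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # interpolate the reference at (possibly fractional) average ranks
    out[, j] <- stats::approx(seq_len(n), ref, xout = r, rule = 2)$y
  }
  out
}

# Blom rank-based inverse normal transform applied across a vector
blom <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Normalize one tissue's expression matrix
#'
#' Applies, in order: `log2(x + 1)`, quantile normalization across samples
#' (reference distribution = mean of sorted columns; ties receive the mean
#' of their target quantiles), then a per-gene Blom rank-inverse-normal
#' transform `qnorm((rank - 3/8) / (n + 1/4))`. Genes constant across all
#' samples map to all-zero Blom scores and are reported via a warning.
#'
#' @param mat A [tissue_matrix()] of nonnegative values.
#' @return A [tissue_matrix()] of normalized values (per-gene fibers are
#'   Blom scores; mean approximately 0).
#' @export
normalize_tissue <- function(mat) {
  stopifnot(all(mat >= 0))
  lg <- log2(unclass(mat) + 1)
  qn <- quantile_normalize(lg)
  row_sd <- apply(qn, 1, stats::sd)
  const <- is.na(row_sd) | row_sd == 0
  out <- t(apply(qn, 1, blom))
  dimnames(out) <- dimnames(mat)
  if (any(const)) {
    warning(sum(const), " gene(s) constant across samples map to all-zero ",
            "Blom scores: ", paste(utils::head(rownames(mat)[const], 5),
                                   collapse = ", "))
  }
  tissue_matrix_normalized(out, tissue_label(mat))
}

# internal constructor bypassing the nonnegativity check (Blom scores are
# signed)
tissue_matrix_normalized <- function(values, label) {
  structure(values, tissue_label = label,
            class = c("tissue_matrix", class(values)))
}

#' Assemble the individuals x genes x tissues expression tensor
#'
#' Intersects sample and gene identifiers across the normalized tissue
#' matrices and stacks them into a 3-D array in individuals x genes x
#' tissues order.
#'
#' @param norm_mats Named list of normalized [tissue_matrix()] objects.
#' @return An object of class `expression_tensor`: the array plus
#'   `individual_ids`, `gene_ids`, `tissue_labels` attributes.
#' @export
assemble_tensor <- function(norm_mats) {
  samples <- Reduce(intersect, lapply(norm_mats, colnames))
  genes <- Reduce(intersect, lapply(norm_mats, rownames))
  if (length(samples) == 0 || length(genes) == 0) {
    stop("empty sample or gene intersection across tissues")
  }
  labels <- vapply(norm_mats, tissue_label, character(1))
  arr <- array(NA_real_, c(length(samples), length(genes), length(norm_mats)),
               dimnames = list(samples, genes, labels))
  for (t in seq_along(norm_mats)) {
    arr[, , t] <- t(norm_mats[[t]][genes, samples, drop = FALSE])
  }
  structure(arr, individual_ids = samples, gene_ids = genes,
            tissue_labels = labels,
            class = c("expression_tensor", "array"))
}

#' One-call preprocessing from raw tissue matrices to a tensor
#'
#' Runs gene filtering, per-tissue outlier-sample removal, normalization and
#' tensor assembly in the standard order.
#'
#' @inheritParams filter_genes
#' @param outlier_sd_mult Multiplier for [detect_outlier_samples()];
#'   `Inf` disables outlier removal.
#' @return An `expression_tensor`.
#' @export
prep_tensor <- function(tissue_mats, mito_gene_ids = character(),
                        median_floor = 0.1, sd_mult = 3, zero_fraction = 0.2,
                        zero_rule = c("all", "any"), outlier_sd_mult = 3) {
  zero_rule <- match.arg(zero_rule)
  keep_genes <- filter_genes(tissue_mats, mito_gene_ids, median_floor,
                             sd_mult, zero_fraction, zero_rule)
  norm <- lapply(tissue_mats, function(m) {
    m2 <- tissue_matrix(unclass(m)[keep_genes, , drop = FALSE],
                        tissue_label(m))
    if (is.finite(outlier_sd_mult)) {
      out <- detect_outlier_samples(m2, outlier_sd_mult)
      if (length(out)) {
        m2 <- tissue_matrix(unclass(m2)[, setdiff(colnames(m2), out),
                                        drop = FALSE], tissue_label(m2))
      }
    }
    normalize_tissue(m2)
  })
  assemble_tensor(norm)
}
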