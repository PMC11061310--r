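#' One-sided Fisher overrepresentation test
#'
#' Hypergeometric upper-tail p-value for the overlap between a query and a
#' target gene set within a declared universe, with fold enrichment
#' `(overlap / |query|) / (|target| / |universe|)`.
#'
#' @param query,target Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector defining the gene universe.
#' @return One-row tibble: overlap, n_query, n_target, n_universe,
#'   fold_enrichment, fisher_p.
#' @export
fisher_overrepresentation <- function(query, target, universe) {
  if (length(universe) == 0 || length(query) == 0 || length(target) == 0) {
    stop("query, target and universe must be nonempty")
  }
  stopifnot(all(query %in% universe), all(target %in% universe))
  query <- unique(query); target <- unique(target)
  universe <- unique(universe)
  k <- length(intersect(query, target))
  nq <- length(query); nt <- length(target); nu <- length(universe)
  p <- stats::phyper(k - 1, nt, nu - nt, nq, lower.tail = FALSE)
  tibble::tibble(overlap = k, n_query = nq, n_target = nt, n_universe = nu,
                 fold_enrichment = (k / nq) / (nt / nu), fisher_p = p)
}

#' Permutation enrichment with a uniform null
#'
#' Draws `n_perm` uniformly random gene sets of the query's size from the
#' universe and compares the observed overlap with the target to the null
#' overlap distribution. The empirical p-value uses the add-one rule
#' `(1 + #{null >= observed}) / (1 + n_perm)`, so it can never be zero and
#' its minimum is `1 / (n_perm + 1)`.
#'
#' @inheritParams fisher_overrepresentation
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble: Fisher fields plus empirical_p, n_perm, seed.
#' @export
empirical_enrichment <- function(query, target, universe, n_perm = 10000,
                                 seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  base <- fisher_overrepresentation(query, target, universe)
  universe <- unique(universe)
  in_target <- universe %in% unique(target)
  nq <- base$n_query
  set.seed(seed)
  null_overlap <- vapply(seq_len(n_perm), function(i) {
    sum(in_target[sample.int(length(universe), nq)])
  }, integer(1))
  dplyr::mutate(base,
                empirical_p = (1 + sum(null_overlap >= base$overlap)) /
                  (1 + n_perm),
                n_perm = n_perm, seed = as.integer(seed))
}

# joint quantile bins over (gc, length, mean_expr) with greedy merging of
# bins too small to supply their quota of matched genes
make_joint_bins <- function(covariates, n_bins) {
  cm <- as.matrix(covariates[, c("gc", "length", "mean_expr")])
  sc <- scale(cm)
  sc[, attr(sc, "scaled:scale") == 0] <- 0
  bin_of <- apply(cm, 2, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                  n_bins + 1)))
    if (length(br) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  })
  id <- apply(bin_of, 1, paste, collapse = "-")
  centroid <- stats::aggregate(sc, list(bin = id), mean)
  list(id = id, centroid = centroid, scaled = sc)
}

merge_small_bins <- function(bins, need) {
  # need: named vector of required draws per bin; merge undersized bins
  # into their nearest bin by covariate centroid until every quota fits
  id <- bins$id
  repeat {
    need <- tapply(need, names(need), sum)
    size <- table(id)
    avail <- as.integer(size[names(need)])
    avail[is.na(avail)] <- 0L
    bad <- names(need)[avail < need]
    if (length(bad) == 0) break
    b <- bad[1]
    cen <- stats::aggregate(bins$scaled, list(bin = id), mean)
    me <- as.numeric(cen[cen$bin == b, -1])
    others <- cen[cen$bin != b, , drop = FALSE]
    if (nrow(others) == 0) stop("cannot merge bins further")
    dd <- rowSums(sweep(as.matrix(others[, -1, drop = FALSE]), 2, me)^2)
    tgt <- others$bin[which.min(dd)]
    id[id == b] <- tgt
    names(need)[names(need) == b] <- tgt
  }
  list(id = id, need = stats::setNames(as.integer(need), names(need)))
}

#' Permutation enrichment with covariate-matched nulls
#'
#' Like [empirical_enrichment()], but each null gene set matches the query's
#' distribution of GC content, gene length and mean expression: universe
#' genes are binned by joint quantile bins of the three covariates
#' (`n_bins` per covariate), and each null set draws, for every query gene,
#' a gene from the same joint bin without replacement within the null set.
#' Bins too small to supply their quota are merged into the nearest bin by
#' covariate centroid.
#'
#' @inheritParams empirical_enrichment
#' @param covariates Tibble with `gene_id`, `gc`, `length`, `mean_expr`
#'   covering every universe gene.
#' @param n_bins Quantile bins per covariate (default 10).
#' @return One-row tibble as [empirical_enrichment()].
#' @export
matched_null_enrichment <- function(query, target, universe, covariates,
                                    n_perm = 10000, n_bins = 10, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  universe <- unique(universe)
  stopifnot(all(universe %in% covariates$gene_id))
  base <- fisher_overrepresentation(query, target, universe)
  cv <- covariates[match(universe, covariates$gene_id), , drop = FALSE]
  bins <- make_joint_bins(cv, n_bins)
  q_idx <- match(unique(query), universe)
  need_tab <- table(bins$id[q_idx])
  need <- stats::setNames(as.integer(need_tab), names(need_tab))
  merged <- merge_small_bins(bins, need)
  quota <- merged$need
  members <- split(seq_along(universe), merged$id)[names(quota)]
  in_target <- universe %in% unique(target)
  set.seed(seed)
  null_overlap <- vapply(seq_len(n_perm), function(i) {
    picked <- unlist(lapply(seq_along(quota), function(b) {
      mem <- members[[b]]
      mem[sample.int(length(mem), quota[[b]])]
    }), use.names = FALSE)
    sum(in_target[picked])
  }, integer(1))
  dplyr::mutate(base,
                empirical_p = (1 + sum(null_overlap >= base$overlap)) /
                  (1 + n_perm),
                n_perm = n_perm, seed = as.integer(seed))
}

#' Competitive mean-rank gene-set test
#'
#' Compares the ranks of a per-gene score (e.g. a cell-type specificity
#' index) inside a query gene set against the remaining universe genes: a
#' Wilcoxon rank-sum statistic with a tie-corrected normal approximation.
#' With all scores tied the statistic carries no information and the
#' p-value is 0.5 (one-sided) or 1 (two-sided).
#'
#' @param scores Named numeric vector of per-gene scores over the universe.
#' @param query Character vector of query genes (proper, nonempty subset of
#'   the universe).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return P-value.
#' @export
mean_rank_geneset_test <- function(scores, query,
                                   alternative = c("greater", "less",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- names(scores)
  stopifnot(!is.null(universe), all(query %in% universe))
  query <- unique(query)
  if (length(query) == length(universe)) stop("query equals the universe")
  n <- length(universe)
  nq <- length(query)
  r <- rank(scores, ties.method = "average")
  w <- sum(r[universe %in% query])
  mu <- nq * (n + 1) / 2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  v <- nq * (n - nq) / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) {
    return(switch(alternative, greater = 0.5, less = 0.5, two.sided = 1))
  }
  z <- (w - mu) / sqrt(v)
  switch(alternative,
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z),
         two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Mean-rank specificity screen across components and cell types
#'
#' Applies [mean_rank_geneset_test()] to every (gene set, cell type)
#' combination and Benjamini-Hochberg adjusts the p-values across the whole
#' family, matching the convention of correcting jointly over components
#' and cell types.
#'
#' @param specificity Matrix of specificity indices, cell types as rows,
#'   universe genes as columns.
#' @param gene_sets Named list of gene-id vectors.
#' @param alternative Passed to [mean_rank_geneset_test()].
#' @return Tibble: gene_set, cell_type, p, p_fdr.
#' @export
mean_rank_screen <- function(specificity, gene_sets,
                             alternative = "greater") {
  res <- purrr::map_dfr(names(gene_sets), function(gs) {
    purrr::map_dfr(rownames(specificity), function(ct) {
      tibble::tibble(gene_set = gs, cell_type = ct,
                     p = mean_rank_geneset_test(specificity[ct, ],
                                                gene_sets[[gs]],
                                                alternative))
    })
  })
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}
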