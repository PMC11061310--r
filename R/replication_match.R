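#' Jaccard index of two gene sets
#'
#' @param a,b Character vectors (at least one nonempty).
#' @return `|a intersect b| / |a union b|` in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) stop("both sets empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Absolute loading correlation over shared genes
#'
#' Sign-invariant Pearson correlation of two components' gene loadings
#' restricted to their shared gene universe.
#'
#' @param x_a,x_b Named numeric loading vectors; at least 3 shared genes
#'   with nonzero variance.
#' @return One-row tibble: abs_r, r2, n_shared.
#' @export
loading_similarity <- function(x_a, x_b) {
  shared <- intersect(names(x_a), names(x_b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  a <- x_a[shared]; b <- x_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant loading vector")
  r <- stats::cor(a, b)
  tibble::tibble(abs_r = abs(r), r2 = r^2, n_shared = length(shared))
}

#' Similarity matrix between two sets of components
#'
#' Builds the discovery x replication similarity matrix under either the
#' Jaccard measure (on membership gene sets) or the absolute
#' loading-correlation measure (on loading vectors restricted to the shared
#' gene universe). The Jaccard of the two gene universes is attached as
#' context.
#'
#' @param discovery,replication For `measure = "jaccard"`: named lists of
#'   gene-id vectors. For `measure = "abs_loading_correlation"`: loading
#'   matrices (components x genes, named).
#' @param measure `"jaccard"` or `"abs_loading_correlation"`.
#' @return Matrix (discovery x replication) with attribute
#'   `gene_universe_overlap` and `measure`.
#' @export
component_similarity <- function(discovery, replication,
                                 measure = c("jaccard",
                                             "abs_loading_correlation")) {
  measure <- match.arg(measure)
  if (measure == "jaccard") {
    S <- outer(seq_along(discovery), seq_along(replication),
               Vectorize(function(i, j) {
                 jaccard_index(discovery[[i]], replication[[j]])
               }))
    dimnames(S) <- list(names(discovery), names(replication))
    uni <- jaccard_index(unique(unlist(discovery)),
                         unique(unlist(replication)))
  } else {
    shared <- intersect(colnames(discovery), colnames(replication))
    if (length(shared) < 3) stop("fewer than 3 shared genes")
    S <- abs(stats::cor(t(discovery[, shared, drop = FALSE]),
                        t(replication[, shared, drop = FALSE])))
    uni <- length(shared) /
      length(union(colnames(discovery), colnames(replication)))
  }
  attr(S, "gene_universe_overlap") <- uni
  attr(S, "measure") <- measure
  S
}

#' Greedy unique pairing of discovery and replication components
#'
#' Processes discovery components in decreasing order of their best
#' available similarity; each takes its highest-similarity replication
#' component among those not yet assigned, which is then discarded. Ties
#' are broken deterministically by replication column order (and discovery
#' row order). With more discovery than replication components the
#' remainder is reported unmatched.
#'
#' @param S Similarity matrix (discovery rows x replication columns),
#'   finite.
#' @return List with `pairs` tibble (discovery, replication, similarity)
#'   and `unmatched` (discovery row names left unpaired).
#' @export
greedy_unique_pairing <- function(S) {
  S <- as.matrix(S)
  stopifnot(all(is.finite(S)))
  dn <- rownames(S); if (is.null(dn)) dn <- sprintf("d%d", seq_len(nrow(S)))
  rn <- colnames(S); if (is.null(rn)) rn <- sprintf("r%d", seq_len(ncol(S)))
  avail <- rep(TRUE, ncol(S))
  left <- seq_len(nrow(S))
  pairs <- list()
  while (length(left) > 0 && any(avail)) {
    best <- vapply(left, function(i) max(S[i, avail]), numeric(1))
    i <- left[which.max(best)]  # first index wins on ties
    j <- which(avail)[which.max(S[i, avail])]
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      discovery = dn[i], replication = rn[j], similarity = S[i, j])
    avail[j] <- FALSE
    left <- setdiff(left, i)
  }
  list(pairs = dplyr::bind_rows(pairs), unmatched = dn[left])
}

#' Permutation p-value for a replication pairing
#'
#' Recomputes the replication measure under a permutation null and applies
#' the add-one empirical rule. Two schemes are available because
#' "permuting the components" differs by measure: for the Jaccard measure,
#' each permutation draws a uniform random discovery set of the same size
#' from the universe; for the correlation measure, each permutation
#' shuffles the gene labels of the discovery loading vector.
#'
#' @param discovery For `"size_matched_random_set"`: the discovery gene-set
#'   (character); for `"gene_label_permutation"`: the discovery loading
#'   vector (named numeric).
#' @param replication The replication gene set, or loading vector.
#' @param universe Gene universe (required for the Jaccard scheme).
#' @param scheme `"size_matched_random_set"` or `"gene_label_permutation"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble: observed, empirical_p, n_perm, scheme, seed.
#' @export
pairing_empirical_p <- function(discovery, replication, universe = NULL,
                                scheme = c("size_matched_random_set",
                                           "gene_label_permutation"),
                                n_perm = 10000, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme == "size_matched_random_set") {
    stopifnot(!is.null(universe))
    universe <- unique(universe)
    obs <- jaccard_index(discovery, replication)
    nd <- length(unique(discovery))
    in_rep <- universe %in% unique(replication)
    nr <- sum(in_rep)
    nulls <- vapply(seq_len(n_perm), function(i) {
      k <- sum(in_rep[sample.int(length(universe), nd)])
      k / (nd + nr - k)
    }, numeric(1))
  } else {
    shared <- intersect(names(discovery), names(replication))
    a <- discovery[shared]; b <- replication[shared]
    obs <- abs(stats::cor(a, b))
    nulls <- vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(sample(a), b))
    }, numeric(1))
  }
  tibble::tibble(observed = obs,
                 empirical_p = (1 + sum(nulls >= obs)) / (1 + n_perm),
                 n_perm = n_perm, scheme = scheme, seed = as.integer(seed))
}

#' Full cross-dataset replication of component sets
#'
#' Convenience wrapper: builds the similarity matrix, runs the greedy
#' unique pairing, and attaches a permutation p-value per pair.
#'
#' @inheritParams component_similarity
#' @param universe Gene universe for the Jaccard permutation scheme
#'   (defaults to the union of all member genes).
#' @param n_perm,seed Permutation settings.
#' @return List: `similarity` matrix, `pairing` tibble with empirical p per
#'   pair, `unmatched`.
#' @export
replicate_components <- function(discovery, replication,
                                 measure = c("jaccard",
                                             "abs_loading_correlation"),
                                 universe = NULL, n_perm = 10000,
                                 seed = 1L) {
  measure <- match.arg(measure)
  S <- component_similarity(discovery, replication, measure)
  gp <- greedy_unique_pairing(S)
  scheme <- if (measure == "jaccard") "size_matched_random_set" else
    "gene_label_permutation"
  if (measure == "jaccard" && is.null(universe)) {
    universe <- union(unique(unlist(discovery)), unique(unlist(replication)))
  }
  pp <- purrr::map_dfr(seq_len(nrow(gp$pairs)), function(i) {
    d_id <- gp$pairs$discovery[i]; r_id <- gp$pairs$replication[i]
    if (measure == "jaccard") {
      pairing_empirical_p(discovery[[d_id]], replication[[r_id]], universe,
                          scheme, n_perm, seed + i)
    } else {
      pairing_empirical_p(discovery[d_id, ], replication[r_id, ], NULL,
                          scheme, n_perm, seed + i)
    }
  })
  pairing <- dplyr::bind_cols(gp$pairs,
                              pp[, c("empirical_p", "n_perm", "scheme")])
  list(similarity = S, pairing = pairing, unmatched = gp$unmatched)
}
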