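#' Sparse three-way factorization of an expression tensor
#'
#' Fits the trilinear model `Y[n,g,t] ~ sum_c A[n,c] B[t,c] X[c,g]` by
#' block coordinate ascent: ridge-regularized least squares for the
#' individual-score matrix `A` and tissue-score matrix `B`, and a
#' variational spike-and-slab update for the gene-loading matrix `X`. The
#' spike-and-slab prior places a point mass at zero and a Gaussian slab on
#' each loading, with per-component inclusion probability and slab variance
#' learned by expectation-maximization, so each component acquires its own
#' level of sparsity and per-gene posterior inclusion probabilities.
#'
#' Components whose posterior inclusion probabilities all fall below
#' `pip_floor` at convergence are pruned. Scale indeterminacy is resolved by
#' rescaling `A` columns to unit standard deviation and `B` columns to unit
#' maximum absolute value after every iteration, pushing all scale into the
#' loadings.
#'
#' @param tensor An `expression_tensor` (individuals x genes x tissues).
#' @param max_components Number of components to start from (default 100;
#'   superfluous components are shrunk away and pruned).
#' @param hyperparams Optional list overriding `pi0` (initial inclusion
#'   probability, 0.1), `v0` (initial slab variance, 1), `ridge` (1e-6),
#'   `pip_floor` (0.1), `tol` (relative objective change, 1e-6) and
#'   `max_iter` (2000).
#' @param seed Integer seed for the random initialization.
#' @param run_id Identifier recorded in the result.
#' @return An object of class `sda_fit`: list with `A` (individuals x
#'   components), `B` (tissues x components), `X` (components x genes),
#'   `pip` (posterior inclusion probabilities, components x genes),
#'   `sigma2`, `objective` (residual-sum-of-squares trace), `n_iter`,
#'   `converged`, `run_id`, `seed`.
#' @export
fit_decomposition <- function(tensor, max_components = 100,
                              hyperparams = list(), seed = 1L, run_id = 1L) {
  stopifnot(inherits(tensor, "expression_tensor"), max_components >= 1)
  hp <- utils::modifyList(list(pi0 = 0.1, v0 = 1, ridge = 1e-6,
                               pip_floor = 0.1, tol = 1e-6, max_iter = 2000),
                          hyperparams)
  Y <- unclass(tensor)
  dn <- dimnames(Y)
  N <- dim(Y)[1]; G <- dim(Y)[2]; TT <- dim(Y)[3]; K <- max_components
  if (stats::sd(Y) == 0) stop("degenerate tensor: all values constant")

  # unfoldings (fixed layouts; see index conventions in comments below)
  Y1 <- matrix(Y, N, G * TT)                      # rows n, cols (g fastest, t)
  Yt <- matrix(Y, N * G, TT)                      # rows (n fastest, g), cols t
  Yx <- matrix(aperm(Y, c(1, 3, 2)), N * TT, G)   # rows (n fastest, t), cols g
  ss_y <- sum(Yx^2)

  set.seed(seed)
  A <- matrix(stats::rnorm(N * K), N, K)
  B <- matrix(stats::rnorm(TT * K), TT, K)
  M <- matrix(0, K, G)          # posterior mean loadings alpha * mu
  Alpha <- matrix(hp$pi0, K, G)
  pi_c <- rep(hp$pi0, K)
  v_c <- rep(hp$v0, K)
  sigma2 <- stats::var(as.vector(Yx))

  rescale <- function() {
    sa <- pmax(apply(A, 2, stats::sd), 1e-12)
    A <<- sweep(A, 2, sa, `/`)
    sb <- pmax(apply(abs(B), 2, max), 1e-12)
    B <<- sweep(B, 2, sb, `/`)
    M <<- M * (sa * sb)
    v_c <<- v_c * (sa * sb)^2
  }

  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(hp$max_iter)) {
    # X update: variational spike-and-slab regression of each gene fiber on
    # W[(n,t),c] = A[n,c] B[t,c]
    W <- vapply(seq_len(K), function(c) as.vector(outer(A[, c], B[, c])),
                numeric(N * TT))
    WtY <- crossprod(W, Yx)
    WtW <- crossprod(W)
    d <- diag(WtW)
    for (c in seq_len(K)) {
      r_c <- WtY[c, ] - drop(WtW[c, ] %*% M) + d[c] * M[c, ]
      s2 <- sigma2 / (d[c] + sigma2 / v_c[c])
      mu <- s2 * r_c / sigma2
      logodds <- log(pi_c[c] / (1 - pi_c[c])) + 0.5 * log(s2 / v_c[c]) +
        mu^2 / (2 * s2)
      alpha <- stats::plogis(logodds)
      Alpha[c, ] <- alpha
      M[c, ] <- alpha * mu
      # EM updates of the component's sparsity level and slab variance
      pi_c[c] <- min(max(mean(alpha), 1 / G), 1 - 1 / G)
      v_c[c] <- max(sum(alpha * (mu^2 + s2)) / max(sum(alpha), 1e-8), 1e-8)
    }
    rss <- ss_y - 2 * sum(WtY * M) + sum(WtW * tcrossprod(M))
    sigma2 <- max(rss / (N * TT * G), 1e-10)

    # A update: ridge least squares on the individual-mode unfolding
    Kr <- vapply(seq_len(K), function(c) as.vector(outer(M[c, ], B[, c])),
                 numeric(G * TT))
    CtC <- tcrossprod(M) * crossprod(B)
    A <- Y1 %*% Kr %*% solve(CtC + hp$ridge * diag(K))

    # B update: ridge least squares on the tissue-mode unfolding
    Dm <- vapply(seq_len(K), function(c) as.vector(outer(A[, c], M[c, ])),
                 numeric(N * G))
    DtD <- crossprod(A) * tcrossprod(M)
    B <- t(solve(DtD + hp$ridge * diag(K), crossprod(Dm, Yt)))

    rescale()
    obj <- c(obj, rss)
    if (it > 1 && abs(obj[it - 1] - rss) <=
          hp$tol * max(abs(obj[it - 1]), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("decomposition did not converge in ", hp$max_iter,
            " iterations; final relative change ",
            signif(abs(diff(utils::tail(obj, 2))) / utils::tail(obj, 1), 3))
  }

  keep <- apply(Alpha, 1, max) >= hp$pip_floor & rowSums(M^2) > 0
  if (!any(keep)) keep[which.max(rowSums(M^2))] <- TRUE
  cn <- sprintf("V%d", seq_len(sum(keep)))
  A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
  M <- M[keep, , drop = FALSE]; Alpha <- Alpha[keep, , drop = FALSE]
  dimnames(A) <- list(dn[[1]], cn)
  dimnames(B) <- list(dn[[3]], cn)
  dimnames(M) <- dimnames(Alpha) <- list(cn, dn[[2]])

  structure(list(A = A, B = B, X = M, pip = Alpha, sigma2 = sigma2,
                 objective = obj, n_iter = length(obj),
                 converged = converged, run_id = run_id,
                 seed = as.integer(seed)),
            class = "sda_fit")
}

#' Repeat the decomposition from independent random starts
#'
#' @inheritParams fit_decomposition
#' @param n_runs Number of runs (seeds `seed + 0:(n_runs-1)`).
#' @return List of `sda_fit` objects.
#' @export
fit_decomposition_runs <- function(tensor, n_runs = 10, max_components = 100,
                                   hyperparams = list(), seed = 1L) {
  lapply(seq_len(n_runs), function(i) {
    fit_decomposition(tensor, max_components, hyperparams,
                      seed = seed + i - 1L, run_id = i)
  })
}

#' Cluster components across runs and combine them
#'
#' Components from different runs are linked when the absolute Pearson
#' correlation of their gene loadings reaches `abs_corr_threshold`;
#' connected components of the resulting graph form clusters. Within a
#' cluster, members are sign-aligned to the first member before averaging
#' individual scores, tissue scores, gene loadings and inclusion
#' probabilities. Clusters spanning at least `min_runs` distinct runs are
#' retained as robust.
#'
#' @param fits List of `sda_fit` objects (at least 2 runs).
#' @param abs_corr_threshold Linkage threshold in (0, 1).
#' @param min_runs Minimum number of distinct runs for a robust cluster.
#' @return An object of class `sda_clusters`: `A`, `B`, `X`, `pip` combined
#'   matrices (robust clusters as columns/rows, named `K1`, `K2`, ...) and a
#'   `clusters` tibble (cluster_id, n_members, n_runs, robust, members).
#' @export
cluster_runs <- function(fits, abs_corr_threshold = 0.6, min_runs = 2) {
  stopifnot(length(fits) >= 2)
  if (abs_corr_threshold <= 0 || abs_corr_threshold >= 1) {
    stop("abs_corr_threshold must lie in (0, 1)")
  }
  comp <- purrr::imap_dfr(fits, function(f, i) {
    tibble::tibble(fit_idx = i, run_id = f$run_id, comp = seq_len(ncol(f$A)))
  })
  m <- nrow(comp)
  L <- t(do.call(rbind, lapply(fits, function(f) f$X)))  # genes x all comps
  cc <- suppressWarnings(abs(stats::cor(L)))
  cc[is.na(cc)] <- 0
  adj <- cc >= abs_corr_threshold
  # connected components by repeated breadth-first expansion
  cluster_id <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (cluster_id[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      cluster_id[i] <- cur
      while (length(frontier)) {
        nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 &
                      cluster_id == 0L)
        cluster_id[nb] <- cur
        frontier <- nb
      }
    }
  }
  comp$cluster <- cluster_id

  combine <- function(idx) {
    # the model is invariant to flipping the sign of any two of (A, B, X)
    # jointly, so members are aligned on X and A independently, with the
    # compensating flip pushed into B
    first <- idx[1]
    f1 <- fits[[comp$fit_idx[first]]]
    a_first <- f1$A[, comp$comp[first]]
    sgn_of <- function(r) if (is.na(r) || r >= 0) 1 else -1
    A <- 0; B <- 0; X <- 0; P <- 0
    for (q in seq_along(idx)) {
      f <- fits[[comp$fit_idx[idx[q]]]]
      c0 <- comp$comp[idx[q]]
      s_x <- sgn_of(suppressWarnings(stats::cor(L[, first], L[, idx[q]])))
      s_a <- sgn_of(suppressWarnings(stats::cor(a_first, f$A[, c0])))
      A <- A + s_a * f$A[, c0]
      B <- B + s_a * s_x * f$B[, c0]
      X <- X + s_x * f$X[c0, ]
      P <- P + f$pip[c0, ]
    }
    list(A = A / length(idx), B = B / length(idx), X = X / length(idx),
         pip = P / length(idx))
  }

  info <- comp |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_runs = dplyr::n_distinct(.data$run_id),
                     .groups = "drop") |>
    dplyr::mutate(robust = .data$n_runs >= min_runs)
  robust_ids <- info$cluster[info$robust]
  combined <- lapply(robust_ids, function(cl) combine(which(comp$cluster == cl)))
  if (length(combined) == 0) stop("no robust clusters found")
  nm <- sprintf("K%d", seq_along(combined))
  A <- do.call(cbind, lapply(combined, `[[`, "A")); colnames(A) <- nm
  B <- do.call(cbind, lapply(combined, `[[`, "B")); colnames(B) <- nm
  X <- do.call(rbind, lapply(combined, `[[`, "X")); rownames(X) <- nm
  P <- do.call(rbind, lapply(combined, `[[`, "pip")); rownames(P) <- nm
  members <- lapply(robust_ids, function(cl) {
    comp[comp$cluster == cl, c("run_id", "comp")]
  })
  names(members) <- nm
  structure(list(A = A, B = B, X = X, pip = P,
                 clusters = dplyr::mutate(info,
                                          cluster_id = paste0("cl",
                                                              .data$cluster)),
                 members = members),
            class = "sda_clusters")
}

#' Scale tissue scores and call tissue activity
#'
#' Divides each component's tissue-score column by its maximum absolute
#' entry, so scaled scores lie in `[-1, 1]` with the largest equal to 1 (or
#' -1), and marks a tissue active when the absolute scaled score reaches
#' `threshold`. A literal min-max affine scaling to `[-1, 1]` is available
#' via `method = "min_max"`.
#'
#' @param B Tissues x components score matrix (finite, no all-zero column).
#' @param threshold Activity cutoff on the scaled score (default 0.5).
#' @param method `"max_abs"` (default) or `"min_max"`.
#' @return Tibble with `component`, `tissue`, `scaled_score`, `active`.
#' @export
tissue_activity <- function(B, threshold = 0.5,
                            method = c("max_abs", "min_max")) {
  method <- match.arg(method)
  B <- as.matrix(B)
  stopifnot(all(is.finite(B)))
  if (any(apply(abs(B), 2, max) == 0)) stop("all-zero tissue-score column")
  scaled <- if (method == "max_abs") {
    sweep(B, 2, apply(abs(B), 2, max), `/`)
  } else {
    apply(B, 2, function(x) {
      if (max(x) == min(x)) return(rep(1, length(x)))
      2 * (x - min(x)) / (max(x) - min(x)) - 1
    })
  }
  dimnames(scaled) <- dimnames(B)
  tibble::as_tibble(as.table(scaled), .name_repair = "minimal") |>
    stats::setNames(c("tissue", "component", "scaled_score")) |>
    dplyr::mutate(active = abs(.data$scaled_score) >= threshold) |>
    dplyr::arrange(.data$component, .data$tissue)
}

#' Gene membership of a component
#'
#' Genes whose posterior inclusion probability reaches `pip_threshold`
#' (median-probability-model convention), ordered by decreasing absolute
#' loading.
#'
#' @param loading Named numeric loading vector (one component's row of `X`).
#' @param pip Named numeric inclusion-probability vector, aligned to
#'   `loading`.
#' @param pip_threshold Inclusion cutoff (default 0.5).
#' @return Character vector of member gene ids (may be empty, with a
#'   warning).
#' @export
component_membership <- function(loading, pip, pip_threshold = 0.5) {
  stopifnot(length(loading) == length(pip))
  sel <- which(pip >= pip_threshold)
  if (length(sel) == 0) {
    warning("empty membership at threshold ", pip_threshold)
    return(character(0))
  }
  ids <- names(loading)
  if (is.null(ids)) ids <- as.character(seq_along(loading))
  ids[sel][order(abs(loading[sel]), decreasing = TRUE)]
}

#' Membership sets for all clusters
#' @param clusters An `sda_clusters` object.
#' @param pip_threshold Inclusion cutoff (default 0.5).
#' @return Named list of gene-id vectors, one per robust cluster.
#' @export
cluster_memberships <- function(clusters, pip_threshold = 0.5) {
  out <- lapply(rownames(clusters$X), function(k) {
    suppressWarnings(component_membership(clusters$X[k, ], clusters$pip[k, ],
                                          pip_threshold))
  })
  names(out) <- rownames(clusters$X)
  out
}
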