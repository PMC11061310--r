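#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decomposition fit
#'
#' Long table of gene loadings with posterior inclusion probabilities.
#'
#' @param x An `sda_fit`.
#' @param ... Unused.
#' @return Tibble: component, gene_id, loading, pip.
#' @export
tidy.sda_fit <- function(x, ...) {
  tibble::tibble(
    component = rep(rownames(x$X), times = ncol(x$X)),
    gene_id = rep(colnames(x$X), each = nrow(x$X)),
    loading = as.vector(x$X),
    pip = as.vector(x$pip)
  ) |>
    dplyr::arrange(.data$component, dplyr::desc(abs(.data$loading)))
}

#' One-row fit summary
#'
#' @param x An `sda_fit`.
#' @param ... Unused.
#' @return Tibble: n_components, n_iter, converged, rss, sigma2.
#' @export
glance.sda_fit <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$A), n_iter = x$n_iter,
                 converged = x$converged,
                 rss = utils::tail(x$objective, 1), sigma2 = x$sigma2)
}

#' Tidy a run-clustering result
#'
#' @param x An `sda_clusters`.
#' @param ... Unused.
#' @return The cluster summary tibble.
#' @export
tidy.sda_clusters <- function(x, ...) x$clusters

#' Tissue-activity heatmap for a decomposition fit or cluster set
#'
#' @param object An `sda_fit` or `sda_clusters`.
#' @param threshold Activity cutoff passed to [tissue_activity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sda_fit <- function(object, threshold = 0.5, ...) {
  ta <- tissue_activity(object$B, threshold)
  ggplot2::ggplot(ta, ggplot2::aes(x = .data$component, y = .data$tissue,
                                   fill = .data$scaled_score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(ta, .data$active),
                        shape = 8, size = 1) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "component", y = "tissue", fill = "scaled\nscore",
                  title = "Tissue activity (starred = |scaled| above cutoff)")
}

#' @rdname autoplot.sda_fit
#' @export
autoplot.sda_clusters <- function(object, threshold = 0.5, ...) {
  autoplot.sda_fit(object, threshold, ...)
}

#' Forest plot of a Fisher-z meta-analysis
#'
#' @param object A `meta_result`.
#' @param cohorts Optional tibble of per-cohort rows (`cohort`, `z`,
#'   `se_z`) drawn alongside the pooled estimate.
#' @param ci_level Interval level for cohort whiskers (default 0.995).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_result <- function(object, cohorts = NULL, ci_level = 0.995,
                                 ...) {
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  df <- tibble::tibble(label = "pooled", z = object$pooled_z,
                       lo = object$ci_lo, hi = object$ci_hi)
  if (!is.null(cohorts)) {
    df <- dplyr::bind_rows(
      tibble::tibble(label = cohorts$cohort, z = cohorts$z,
                     lo = cohorts$z - zc * cohorts$se_z,
                     hi = cohorts$z + zc * cohorts$se_z),
      df)
  }
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(x = "Fisher z", y = NULL)
}

#' Patlak diagnostic plot
#'
#' Draws the Patlak coordinates with the fitted linear phase.
#'
#' @param tac TAC tibble as for [patlak_ki()].
#' @param t_star Linear-phase start (minutes).
#' @return A ggplot.
#' @export
plot_patlak <- function(tac, t_star = 20) {
  xint <- cum_trapz0(tac$frame_mid_min, tac$ref_activity)
  df <- tibble::tibble(x = xint / tac$ref_activity,
                       y = tac$roi_activity / tac$ref_activity,
                       used = tac$frame_mid_min >= t_star)
  fit <- patlak_ki(tac, t_star)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$used)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$ki, intercept = fit$intercept) +
    ggplot2::labs(x = "normalized integrated reference activity",
                  y = "ROI / reference activity",
                  colour = "in linear phase",
                  title = sprintf("Patlak fit: Ki = %.4g /min", fit$ki))
}

#' @importFrom rlang .data
NULL
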