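#' Patlak-Gjedde graphical Ki estimation with a reference region
#'
#' Ordinary least squares of `y(T) = C_roi(T) / C_ref(T)` on
#' `x(T) = int_0^T C_ref dt / C_ref(T)` over frames with mid-time at least
#' `t_star`; the slope estimates the influx rate constant Ki and the
#' intercept the distribution-volume term. The running integral uses the
#' trapezoid rule on frame mid-times anchored at (0, 0), so noiseless
#' Patlak-form curves are recovered exactly.
#'
#' @param tac Tibble with `frame_mid_min`, `roi_activity`, `ref_activity`
#'   (as produced by [simulate_tac()]).
#' @param t_star Start of the linear phase in minutes (default 20).
#' @return One-row tibble of class `patlak_result`: ki, intercept, r2_fit,
#'   t_star, n_frames_used.
#' @export
patlak_ki <- function(tac, t_star = 20) {
  stopifnot(all(diff(tac$frame_mid_min) > 0))
  use <- tac$frame_mid_min >= t_star
  if (sum(use) < 3) stop("fewer than 3 frames past t_star")
  if (any(tac$ref_activity[use] <= 0)) stop("non-positive reference activity")
  xint <- cum_trapz0(tac$frame_mid_min, tac$ref_activity)
  x <- xint[use] / tac$ref_activity[use]
  y <- tac$roi_activity[use] / tac$ref_activity[use]
  fit <- stats::lm(y ~ x)
  out <- tibble::tibble(ki = unname(stats::coef(fit)[2]),
                        intercept = unname(stats::coef(fit)[1]),
                        r2_fit = summary(fit)$r.squared,
                        t_star = t_star, n_frames_used = sum(use))
  class(out) <- c("patlak_result", class(out))
  out
}

#' ROI phenotype-PRS association for one cohort
#'
#' Multiple linear regression of an ROI phenotype (Ki, BOLD contrast, ...)
#' on a polygenic score plus covariates. The PRS t-statistic is converted
#' to a correlation via `r = sqrt(t^2 / (t^2 + DF))` carrying the sign of
#' t, then Fisher-z transformed; `se_z = 1 / sqrt(n - 3)` by default, or
#' `1 / sqrt(DF - 1)` to acknowledge covariate-consuming regressions.
#'
#' @param data Data frame holding the phenotype, PRS and covariates.
#' @param phenotype,prs Column names of the outcome and score.
#' @param covariates Character vector of covariate column names.
#' @param cohort Cohort label stored in the result.
#' @param se_method `"n_minus_3"` (default) or `"df_minus_1"`.
#' @return One-row tibble of class `cohort_association`: cohort, t, df, r,
#'   z, se_z, n.
#' @export
roi_association <- function(data, phenotype, prs, covariates = character(),
                            cohort = "cohort1",
                            se_method = c("n_minus_3", "df_minus_1")) {
  se_method <- match.arg(se_method)
  n <- nrow(data)
  stopifnot(n > length(covariates) + 2)
  rhs <- paste(sprintf("`%s`", c(prs, covariates)), collapse = " + ")
  fit <- stats::lm(stats::as.formula(sprintf("`%s` ~ %s", phenotype, rhs)),
                   data = data)
  sm <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit)))) stop("collinear covariates")
  t <- sm[grep(prs, rownames(sm), fixed = TRUE)[1], 3]
  dfree <- fit$df.residual
  r <- sign(t) * sqrt(t^2 / (t^2 + dfree))
  out <- tibble::tibble(
    cohort = cohort, t = t, df = dfree, r = r, z = atanh(r),
    se_z = if (se_method == "n_minus_3") 1 / sqrt(n - 3) else
      1 / sqrt(dfree - 1),
    n = n)
  class(out) <- c("cohort_association", class(out))
  out
}

#' Fixed-effect meta-analysis of Fisher-z correlations
#'
#' Inverse-variance pooling: `w_i = 1 / se_z_i^2`,
#' `pooled_z = sum(w z) / sum(w)`, `se = 1 / sqrt(sum(w))`, a normal
#' confidence interval at `ci_level`, a two-sided p-value, the pooled
#' correlation `tanh(pooled_z)` and its square, and a Bonferroni-adjusted
#' p over `m_tests` comparisons (the 10 PRS thresholds by default).
#'
#' @param cohorts Tibble of per-cohort results with columns `z` and `se_z`
#'   (as from [roi_association()]).
#' @param ci_level Confidence level (default 0.995, i.e. a 99.5% interval).
#' @param m_tests Bonferroni family size (default 10).
#' @return One-row tibble of class `meta_result`: pooled_z, se_pooled,
#'   ci_lo, ci_hi, p, p_bonferroni, pooled_r, r2, n_cohorts.
#' @export
fixed_effect_meta <- function(cohorts, ci_level = 0.995, m_tests = 10) {
  stopifnot(nrow(cohorts) >= 1)
  if (any(cohorts$se_z <= 0)) stop("non-positive standard error")
  w <- 1 / cohorts$se_z^2
  pooled_z <- sum(w * cohorts$z) / sum(w)
  se <- 1 / sqrt(sum(w))
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  p <- 2 * stats::pnorm(abs(pooled_z) / se, lower.tail = FALSE)
  out <- tibble::tibble(
    pooled_z = pooled_z, se_pooled = se,
    ci_lo = pooled_z - zc * se, ci_hi = pooled_z + zc * se,
    p = p, p_bonferroni = bonferroni_adjust(p, m_tests),
    pooled_r = tanh(pooled_z), r2 = tanh(pooled_z)^2,
    n_cohorts = nrow(cohorts))
  class(out) <- c("meta_result", class(out))
  out
}

#' Reporting conversions
#'
#' `z_to_r2()` converts a pooled Fisher-z to the variance-explained scale
#' (`tanh(z)^2`); `bonferroni_adjust()` multiplies a p-value by the family
#' size and caps at 1.
#'
#' @param z Fisher-z value.
#' @return `z_to_r2`: `tanh(z)^2`.
#' @export
z_to_r2 <- function(z) tanh(z)^2

#' @rdname z_to_r2
#' @param p P-value.
#' @param m Family size, `m >= 1`.
#' @return `bonferroni_adjust`: `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}
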