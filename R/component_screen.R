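#' Power of a two-sided correlation test (Fisher-z approximation)
#'
#' `power = Phi(atanh(r) * sqrt(n - 3) - z_{1 - alpha/2})` plus the
#' (negligible) opposite tail. Used to translate a reference confounder
#' effect size into an equivalently powered p-value threshold at the
#' study's own sample size.
#'
#' @param r True correlation, `0 <= r < 1`.
#' @param n Sample size, `n >= 4`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in `[0, 1]`.
#' @export
correlation_power <- function(r, n, alpha) {
  stopifnot(r >= 0, r < 1, n >= 4, alpha > 0, alpha < 1)
  zc <- stats::qnorm(1 - alpha / 2)
  delta <- atanh(r) * sqrt(n - 3)
  stats::pnorm(delta - zc) + stats::pnorm(-delta - zc)
}

# fit one multiple regression of a score on a covariate data frame and
# return the per-coefficient summary with the originating variable name
score_regression <- function(score, covariates) {
  df <- data.frame(.score = score, covariates, check.names = FALSE)
  fit <- stats::lm(.score ~ ., data = df)
  mm <- stats::model.matrix(fit)
  var_of_col <- stats::setNames(
    c("(Intercept)", names(covariates))[attr(mm, "assign") + 1],
    colnames(mm))
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    warning("aliased columns dropped: ",
            paste(names(coefs)[is.na(coefs)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 variable = unname(var_of_col[rownames(sm)]),
                 estimate = sm[, 1], t = sm[, 3], p = sm[, 4])
}

#' Filter components associated with technical confounders
#'
#' For each component, regresses its individual scores jointly on all
#' supplied covariates and removes the component when any technical
#' confounder or genomic-eigenvariate coefficient is significant below
#' `p_threshold`. Biological terms (diagnosis, age, sex) never trigger
#' removal. Rank-deficient covariate matrices have aliased columns dropped
#' and reported.
#'
#' @param scores Individuals x components numeric matrix.
#' @param covariates Data frame of covariates (rows aligned to `scores`).
#' @param technical_vars Covariate names whose significance triggers
#'   removal (technical confounders and eigenvariates).
#' @param p_threshold Removal threshold (default 5e-4, the level at which a
#'   reference confounder effect size of 0.274 has 80% power at n = 238).
#' @return List with `kept` (component names) and `report` tibble
#'   (component, removed, offending variable, min p among triggers).
#' @export
confounder_filter <- function(scores, covariates, technical_vars,
                              p_threshold = 5e-4) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(covariates),
            all(technical_vars %in% names(covariates)))
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("K%d", seq_len(ncol(scores)))
  }
  report <- purrr::map_dfr(colnames(scores), function(k) {
    tab <- score_regression(scores[, k], covariates)
    trig <- tab[tab$variable %in% technical_vars, , drop = FALSE]
    hit <- trig[trig$p < p_threshold, , drop = FALSE]
    tibble::tibble(
      component = k,
      removed = nrow(hit) > 0,
      offending = if (nrow(hit)) hit$variable[which.min(hit$p)] else NA,
      p = if (nrow(hit)) min(hit$p) else min(trig$p)
    )
  })
  list(kept = report$component[!report$removed], report = report)
}

#' Diagnosis ANCOVA across components
#'
#' Tests each component's individual scores for a diagnosis effect while
#' adjusting for covariates: an F test comparing the full model with the
#' model without diagnosis. Effect size is classical eta squared
#' (`SS_diagnosis / SS_total`; partial eta squared via
#' `eta2 = "partial"`). P-values are Benjamini-Hochberg adjusted across
#' components. Individuals aged `min_age` or younger are excluded (strict
#' `age > min_age`).
#'
#' @param scores Individuals x components matrix.
#' @param metadata Data frame containing `dx_var`, `age`, and the covariate
#'   columns, rows aligned to `scores`.
#' @param covariates Character vector of covariate column names.
#' @param dx_var Name of the diagnosis column (factor, 2 or more levels).
#' @param min_age Age filter; set `-Inf` to disable.
#' @param eta2 `"classical"` or `"partial"`.
#' @return Tibble: component, F, df1, df2, p, eta2, p_fdr, dx_sign (sign of
#'   the last diagnosis-level coefficient).
#' @export
diagnosis_ancova <- function(scores, metadata, covariates,
                             dx_var = "diagnosis", min_age = 17,
                             eta2 = c("classical", "partial")) {
  eta2 <- match.arg(eta2)
  scores <- as.matrix(scores)
  keep <- if (is.finite(min_age)) metadata$age > min_age else
    rep(TRUE, nrow(metadata))
  md <- metadata[keep, , drop = FALSE]
  sc <- scores[keep, , drop = FALSE]
  if (length(unique(md[[dx_var]])) < 2) {
    stop("fewer than 2 diagnosis groups after the age filter")
  }
  if (is.null(colnames(sc))) colnames(sc) <- sprintf("K%d", seq_len(ncol(sc)))
  cov_df <- md[, covariates, drop = FALSE]
  res <- purrr::map_dfr(colnames(sc), function(k) {
    df <- data.frame(.score = sc[, k], .dx = md[[dx_var]], cov_df,
                     check.names = FALSE)
    full <- stats::lm(.score ~ ., data = df)
    red <- stats::lm(.score ~ . - .dx, data = df)
    an <- stats::anova(red, full)
    ss_dx <- an$`Sum of Sq`[2]
    ss_res <- an$RSS[2]
    ss_tot <- sum((df$.score - mean(df$.score))^2)
    fstat <- an$F[2]
    co <- stats::coef(full)
    dx_co <- co[grep("^\\.dx", names(co))]
    tibble::tibble(
      component = k, F = fstat, df1 = an$Df[2], df2 = an$Res.Df[2],
      p = an$`Pr(>F)`[2],
      eta2 = if (eta2 == "classical") ss_dx / ss_tot else
        ss_dx / (ss_dx + ss_res),
      dx_sign = sign(dx_co[length(dx_co)])
    )
  })
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Direction-constrained PRS association for a component
#'
#' Regresses component scores on the polygenic risk score plus covariates
#' and reports a one-tailed test in the diagnosis-consistent direction:
#' effects opposite to the diagnosis association are, by construction,
#' never significant (one-tailed p > 0.5).
#'
#' @param scores Numeric vector of one component's individual scores.
#' @param prs Numeric PRS vector (non-constant), aligned to `scores`.
#' @param covariates Data frame of covariates.
#' @param dx_sign +1 or -1: sign of the diagnosis effect on this component.
#' @return Tibble: t, df, p_one_tailed, partial_r2, direction_consistent.
#' @export
prs_association <- function(scores, prs, covariates = NULL, dx_sign = 1) {
  if (stats::sd(prs) == 0) stop("constant PRS")
  stopifnot(dx_sign %in% c(-1, 1))
  df <- if (is.null(covariates)) data.frame(.score = scores, .prs = prs) else
    data.frame(.score = scores, .prs = prs, covariates, check.names = FALSE)
  fit <- stats::lm(.score ~ ., data = df)
  sm <- summary(fit)$coefficients
  t <- sm[".prs", 3]
  dfree <- fit$df.residual
  p1 <- if (dx_sign > 0) stats::pt(t, dfree, lower.tail = FALSE) else
    stats::pt(t, dfree)
  tibble::tibble(t = t, df = dfree, p_one_tailed = p1,
                 partial_r2 = t^2 / (t^2 + dfree),
                 direction_consistent = sign(t) == dx_sign)
}

#' Component score regression on named gene or transcript expression
#'
#' Fits a multiple linear regression of component individual scores on
#' per-tissue expression of selected genes (or transcripts) plus
#' covariates, optionally with diagnosis main and interaction terms
#' (diagnosis x each expression term and diagnosis x age), and returns the
#' per-term coefficient table with `partial R^2 = t^2 / (t^2 + DF)`.
#' Dropping the diagnosis terms (`dx_var = NULL`) gives the controls-only
#' model; transcript-level columns are handled identically.
#'
#' @param scores Numeric vector of component scores.
#' @param expression Data frame of expression columns (one per
#'   gene x tissue or transcript x tissue), rows aligned to `scores`.
#' @param metadata Data frame holding covariates (and diagnosis/age when
#'   interactions are requested).
#' @param covariates Character vector of covariate column names in
#'   `metadata`.
#' @param dx_var Name of the diagnosis column for interaction terms, or
#'   `NULL` for the controls-only structure.
#' @param age_var Age column used for the diagnosis x age interaction.
#' @return Tibble: term, estimate, t, df, p, partial_r2.
#' @export
gene_expression_association <- function(scores, expression, metadata,
                                        covariates, dx_var = "diagnosis",
                                        age_var = "age") {
  stopifnot(length(scores) == nrow(expression))
  expr_terms <- names(expression)
  df <- data.frame(.score = scores, expression,
                   metadata[, unique(c(covariates,
                                       if (!is.null(dx_var)) c(dx_var,
                                                               age_var))),
                            drop = FALSE],
                   check.names = FALSE)
  rhs <- if (is.null(dx_var)) {
    paste(c(sprintf("`%s`", expr_terms), covariates), collapse = " + ")
  } else {
    paste(c(sprintf("`%s` * `%s`", dx_var, expr_terms),
            sprintf("`%s` * `%s`", dx_var, age_var),
            setdiff(covariates, c(dx_var, age_var))), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".score ~", rhs)), data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("perfect collinearity among model terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  dfree <- fit$df.residual
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], t = sm[, 3],
                 df = dfree, p = sm[, 4],
                 partial_r2 = sm[, 3]^2 / (sm[, 3]^2 + dfree))
}
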