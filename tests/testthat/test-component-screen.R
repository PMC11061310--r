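test_that("correlation power reproduces the reference derivation", {
  # the reference confounder effect size at the study's own sample size
  expect_equal(correlation_power(0.274, 238, 5e-4), 0.80, tolerance = 0.01)
  # power equals the level under the null
  expect_equal(correlation_power(0, 100, 0.05), 0.05, tolerance = 1e-10)
  # alpha -> 1 gives power -> 1
  expect_gt(correlation_power(0.1, 50, 1 - 1e-12), 0.999)
  # monotone in r, n and alpha
  expect_true(all(diff(sapply(c(.1, .2, .3, .4),
                              correlation_power, n = 100,
                              alpha = .05)) > 0))
  expect_true(all(diff(sapply(c(20, 50, 100, 200),
                              function(n) correlation_power(.2, n, .05)))
                  > 0))
  expect_true(all(diff(sapply(c(1e-4, 1e-3, .01, .05),
                              function(a) correlation_power(.2, 100, a)))
                  > 0))
  expect_error(correlation_power(1.2, 100, .05))
})

test_that("confounder filter removes contaminated, keeps diagnosis-only components", {
  set.seed(8)
  n <- 200
  covs <- data.frame(diagnosis = factor(rep(c("NC", "SCZ"), each = n / 2)),
                     age = runif(n, 18, 80), sex = factor(rbinom(n, 1, .5)),
                     rin = runif(n, 6, 9), pmi = runif(n, 5, 50),
                     ge1 = rnorm(n))
  tech <- c("rin", "pmi", "ge1")
  scores <- cbind(
    clean = rnorm(n),
    contaminated = 0.8 * scale(covs$rin)[, 1] + 0.6 * rnorm(n),
    dx_only = 0.8 * (covs$diagnosis == "SCZ") + rnorm(n)
  )
  out <- confounder_filter(scores, covs, technical_vars = tech)
  expect_true("contaminated" %in%
                out$report$component[out$report$removed])
  expect_true(all(c("clean", "dx_only") %in% out$kept))
  expect_equal(out$report$offending[out$report$component == "contaminated"],
               "rin")
})

test_that("confounder filter is calibrated under the null", {
  set.seed(3)
  n <- 150
  covs <- data.frame(rin = runif(n), pmi = runif(n), ge1 = rnorm(n))
  scores <- matrix(rnorm(n * 1000), n, 1000)
  out <- confounder_filter(scores, covs, technical_vars = names(covs),
                           p_threshold = 0.05)
  # three independent tests per component at alpha = 0.05:
  # expected removal fraction 1 - 0.95^3 ~ 0.143
  frac <- mean(out$report$removed)
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.20)
})

test_that("diagnosis ANCOVA: calibration, power, BH and the age filter", {
  set.seed(4)
  n <- 200
  md <- data.frame(diagnosis = factor(rep(c("NC", "SCZ"), each = n / 2)),
                   age = runif(n, 18, 80), sex = factor(rbinom(n, 1, .5)))

  # null calibration across 500 independent null components
  null_scores <- matrix(rnorm(n * 500), n, 500)
  res0 <- diagnosis_ancova(null_scores, md, covariates = c("age", "sex"))
  t1e <- mean(res0$p < 0.05)
  expect_gt(t1e, 0.03); expect_lt(t1e, 0.07)

  # planted standardized shift 0.8: overwhelmingly significant
  shift <- 0.8 * (md$diagnosis == "SCZ")
  ps <- sapply(1:20, function(i) {
    diagnosis_ancova(cbind(rnorm(n) + shift), md, c("age", "sex"))$p
  })
  expect_gte(mean(ps < 1e-4), 0.95)

  # effect size consistent with the F statistic
  one <- diagnosis_ancova(cbind(rnorm(n) + shift), md, c("age", "sex"),
                          eta2 = "partial")
  expect_equal(one$eta2, one$F / (one$F + one$df2), tolerance = 1e-10)

  # age filter empties nothing here but excludes 17-year-olds strictly
  md2 <- md; md2$age[1:5] <- 17
  r2 <- diagnosis_ancova(cbind(rnorm(n)), md2, c("age", "sex"))
  expect_equal(r2$df2, (n - 5) - 4)
})

test_that("Benjamini-Hochberg behaves as the direct formula on a known case", {
  # computed by the BH step-up rule by hand: p_(i) * m / i, cummin from top
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(1)
  p <- runif(30)
  res <- diagnosis_ancova(
    matrix(rnorm(50 * 3), 50, 3),
    data.frame(diagnosis = factor(rep(c("a", "b"), 25)),
               age = runif(50, 20, 60)),
    covariates = "age")
  expect_true(all(res$p_fdr >= res$p))
  expect_false(is.unsorted(res$p_fdr[order(res$p)]))
})

test_that("PRS association: directionality, power and the partial R2 identity", {
  set.seed(6)
  n <- 100
  covs <- data.frame(age = runif(n, 20, 70))

  # planted consistent effect r = 0.3: one-tailed p < 0.05 most seeds
  hits <- sapply(1:30, function(i) {
    prs <- rnorm(n)
    sc <- 0.3 * prs + sqrt(1 - 0.09) * rnorm(n)
    prs_association(sc, prs, covs, dx_sign = 1)$p_one_tailed < 0.05
  })
  expect_gte(mean(hits), 0.8)

  # inconsistent direction: one-tailed p > 0.5, flagged inconsistent
  prs <- rnorm(n)
  sc <- -0.5 * prs + rnorm(n)
  res <- prs_association(sc, prs, covs, dx_sign = 1)
  expect_gt(res$p_one_tailed, 0.5)
  expect_false(res$direction_consistent)

  # partial R2 identity against the residual-SS route
  sc2 <- 0.4 * prs + rnorm(n)
  r1 <- prs_association(sc2, prs, covs, dx_sign = 1)
  full <- lm(sc2 ~ prs + age, data = cbind(covs, sc2 = sc2, prs = prs))
  red <- lm(sc2 ~ age, data = cbind(covs, sc2 = sc2))
  r2_ss <- (sum(resid(red)^2) - sum(resid(full)^2)) / sum(resid(red)^2)
  expect_equal(r1$partial_r2, r2_ss, tolerance = 1e-10)
  expect_equal(prs_association(sc2, prs, covs, 1)$partial_r2,
               r1$t^2 / (r1$t^2 + r1$df), tolerance = 1e-12)
  expect_error(prs_association(sc2, rep(1, n), covs, 1), "constant")

  # t statistics invariant to affine covariate rescaling
  covs2 <- data.frame(age = 10 * covs$age + 100)
  expect_equal(prs_association(sc2, prs, covs2, 1)$t, r1$t,
               tolerance = 1e-10)
})

test_that("gene-expression regression recovers planted terms and nests models", {
  set.seed(7)
  n <- 200
  md <- data.frame(diagnosis = factor(rep(c("NC", "SCZ"), each = n / 2)),
                   age = runif(n, 18, 80), sex = factor(rbinom(n, 1, .5)),
                   pmi = runif(n, 5, 50))
  expr <- data.frame(geneA_CN = rnorm(n), geneB_CN = rnorm(n))
  score <- 0.5 * expr$geneA_CN + rnorm(n)
  tab <- gene_expression_association(score, expr, md,
                                     covariates = c("sex", "pmi"))
  a_row <- tab[tab$term == "geneA_CN", ]
  expect_gt(a_row$t, 0)
  expect_lt(a_row$p, 0.01)

  # permuted expression: gene-term p roughly uniform
  ps <- sapply(1:60, function(i) {
    expr_p <- data.frame(geneA_CN = sample(expr$geneA_CN))
    tb <- gene_expression_association(rnorm(n), expr_p, md,
                                      covariates = c("sex", "pmi"))
    tb$p[tb$term == "geneA_CN"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  # controls-only model equals the full model with diagnosis terms dropped
  ctrl <- md$diagnosis == "NC"
  t_ctrl <- gene_expression_association(score[ctrl], expr[ctrl, ],
                                        md[ctrl, ],
                                        covariates = c("sex", "pmi"),
                                        dx_var = NULL)
  expect_false(any(grepl("diagnosis", t_ctrl$term)))
  expect_true(all(c("geneA_CN", "geneB_CN") %in% t_ctrl$term))
})
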