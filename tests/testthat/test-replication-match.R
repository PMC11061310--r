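test_that("similarity measures: hand values, sign invariance, gene order", {
  expect_equal(jaccard_index(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard_index(letters[1:5], letters[1:5]), 1)
  a <- sprintf("a%02d", 1:20); b <- c(a[1:10], sprintf("b%02d", 1:20))
  expect_equal(jaccard_index(a, b), 10 / 40)
  expect_error(jaccard_index(character(), character()), "empty")

  set.seed(1)
  x <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  expect_equal(loading_similarity(x, -x)$abs_r, 1, tolerance = 1e-12)
  y <- setNames(rnorm(1000), names(x))
  expect_lt(loading_similarity(x, y)$abs_r, 0.1)
  # gene-order invariance
  perm <- sample(names(x))
  expect_equal(loading_similarity(x, y)$abs_r,
               loading_similarity(x[perm], y)$abs_r, tolerance = 1e-12)
  # planted population r2 = 0.5 recovered at length 2000
  x2 <- setNames(rnorm(2000), sprintf("h%04d", 1:2000))
  y2 <- 0.5 * x2 + rnorm(2000, sd = 0.5)  # var ratio gives r2 = 0.5
  expect_lt(abs(loading_similarity(x2, y2)$r2 - 0.5), 0.1)
  expect_error(loading_similarity(x[1:2], y[1:2]), "shared")
})

test_that("greedy pairing follows the stated rule and matches the oracle", {
  S <- matrix(c(0.9, 0.2, 0.8, 0.7), 2, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("r1", "r2")))
  gp <- greedy_unique_pairing(S)
  expect_equal(gp$pairs$replication, c("r1", "r2"))
  expect_equal(gp$pairs$similarity, c(0.9, 0.7))

  # diagonal-dominant: identity pairing
  D <- diag(c(.9, .8, .7)) + 0.01
  dimnames(D) <- list(paste0("d", 1:3), paste0("r", 1:3))
  gpd <- greedy_unique_pairing(D)
  expect_equal(gpd$pairs$replication[match(paste0("d", 1:3),
                                           gpd$pairs$discovery)],
               paste0("r", 1:3))

  # tie broken by replication column order, deterministically
  Tt <- matrix(c(0.5, 0.5), 1, dimnames = list("d1", c("r1", "r2")))
  expect_equal(greedy_unique_pairing(Tt)$pairs$replication, "r1")

  # oracle equality on random small matrices; injective matching; more
  # total similarity than random matchings nearly always
  set.seed(2)
  beats <- 0; total <- 0
  for (i in 1:30) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    # background noise plus a planted strong correspondence, the structure
    # replication similarity matrices actually show
    S <- matrix(runif(n * m, 0, 0.3), n, m,
                dimnames = list(paste0("d", 1:n), paste0("r", 1:m)))
    k0 <- min(n, m)
    S[cbind(sample(n, k0), sample(m, k0))] <- runif(k0, 0.6, 0.95)
    gp <- greedy_unique_pairing(S)
    or <- greedy_oracle(S)
    expect_equal(as.data.frame(gp$pairs[order(gp$pairs$discovery), ]),
                 or[order(or$discovery), ], ignore_attr = TRUE)
    expect_false(anyDuplicated(gp$pairs$replication) > 0)
    expect_false(anyDuplicated(gp$pairs$discovery) > 0)
    expect_identical(greedy_unique_pairing(S)$pairs, gp$pairs)
    # compare with random injective matchings
    k <- nrow(gp$pairs)
    for (j in 1:20) {
      rows <- sample(n, k); cols <- sample(m, k)
      total <- total + 1
      if (sum(gp$pairs$similarity) >= sum(S[cbind(rows, cols)])) {
        beats <- beats + 1
      }
    }
  }
  expect_gte(beats / total, 0.99)

  # more discovery than replication: remainder unmatched
  S2 <- matrix(runif(6), 3, 2,
               dimnames = list(paste0("d", 1:3), paste0("r", 1:2)))
  expect_length(greedy_unique_pairing(S2)$unmatched, 1)
})

test_that("pairing permutation p: floor, calibration and planted recovery", {
  set.seed(3)
  u <- sprintf("g%04d", 1:800)
  shared <- sample(u, 60)
  disc <- c(shared, sample(setdiff(u, shared), 20))
  repl <- c(shared, sample(setdiff(u, c(shared, disc)), 20))
  res <- pairing_empirical_p(disc, repl, u, "size_matched_random_set",
                             n_perm = 2000, seed = 4)
  expect_equal(res$empirical_p, 1 / 2001, tolerance = 1e-12)

  # null calibration for the correlation scheme
  x <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  ps <- sapply(1:100, function(i) {
    set.seed(100 + i)
    y <- setNames(rnorm(300), names(x))
    pairing_empirical_p(y, x, scheme = "gene_label_permutation",
                        n_perm = 200, seed = i)$empirical_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("two synthetic datasets sharing a component replicate end to end", {
  # one shared sparse component, one dataset-specific component each
  set.seed(6)
  g <- sprintf("g%04d", 1:800)
  shared_load <- setNames(numeric(800), g)
  shared_load[sample(800, 40)] <- rnorm(40, 2)
  mk_comps <- function(seed) {
    set.seed(seed)
    own <- setNames(numeric(800), g)
    own[sample(800, 40)] <- rnorm(40, 2)
    rbind(shared = shared_load + rnorm(800, sd = 0.2), own = own)
  }
  disc <- mk_comps(7); repl <- mk_comps(8)
  S <- component_similarity(disc, repl, "abs_loading_correlation")
  gp <- greedy_unique_pairing(S)
  top <- gp$pairs[gp$pairs$discovery == "shared", ]
  expect_equal(top$replication, "shared")
  pp <- pairing_empirical_p(disc["shared", ], repl["shared", ],
                            scheme = "gene_label_permutation",
                            n_perm = 2000, seed = 9)
  expect_lt(pp$empirical_p, 0.001)
})

test_that("replicate_components wraps the pieces consistently", {
  set.seed(10)
  u <- sprintf("g%03d", 1:400)
  disc <- list(c1 = sample(u, 50), c2 = sample(u, 60))
  repl <- list(k1 = c(disc$c1[1:40], sample(setdiff(u, disc$c1), 10)),
               k2 = sample(u, 55))
  out <- replicate_components(disc, repl, "jaccard", universe = u,
                              n_perm = 500, seed = 2)
  expect_equal(out$pairing$replication[out$pairing$discovery == "c1"], "k1")
  expect_lt(out$pairing$empirical_p[out$pairing$discovery == "c1"], 0.01)
  expect_equal(attr(out$similarity, "measure"), "jaccard")
})
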