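gwas_row <- function(snp_id, chrom = 1, pos = 1e6, a1 = "A", a2 = "G",
                     beta = 0.1, p = 0.5, maf = 0.25, info = 0.99,
                     is_indel = FALSE) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos, a1 = a1,
                 a2 = a2, beta = beta, p = p, maf = maf, info = info,
                 is_indel = is_indel)
}

test_that("SNP QC applies each exclusion rule on a hand-counted fixture", {
  tab <- dplyr::bind_rows(
    gwas_row("low_maf1", maf = 0.005),
    gwas_row("low_maf2", maf = 0.009),
    gwas_row("low_info", info = 0.85),
    gwas_row("indel", is_indel = TRUE),
    gwas_row("mhc", chrom = 6, pos = 30e6),
    gwas_row("clean1"), gwas_row("clean2", chrom = 6, pos = 24e6),
    gwas_row("clean3", chrom = 6, pos = 34000001)
  )
  out <- snp_qc(tab)
  expect_setequal(out$snp_id, c("clean1", "clean2", "clean3"))
  # boundary: exactly at the MHC edges is excluded
  edge <- snp_qc(dplyr::bind_rows(gwas_row("e1", chrom = 6, pos = 25e6),
                                  gwas_row("e2", chrom = 6, pos = 34e6),
                                  gwas_row("keep")))
  expect_identical(edge$snp_id, "keep")
})

test_that("gene-window mapping is boundary-inclusive and matches brute force", {
  ann <- tibble::tibble(chrom = c(1, 1), start = c(1e6, 5e6),
                        end = c(1.01e6, 5.2e6),
                        gene_id = c("gA", "gB"))
  v <- tibble::tibble(
    snp_id = c("s_up_edge", "s_up_out", "s_in", "s_down_edge",
               "s_down_out", "s_other_chr"),
    chrom = c(1, 1, 1, 1, 1, 2),
    pos = c(1e6 + 1 - 1e5, 1e6 - 1e5, 1.005e6, 1.01e6 + 1e5,
            1.01e6 + 1e5 + 1, 1.005e6))
  hit <- map_snps_to_gene_windows(v, ann, c("gA", "gB"))
  expect_true("s_up_edge" %in% hit)     # exactly 100 kb upstream
  expect_false("s_up_out" %in% hit)     # 100,001 bp upstream
  expect_true(all(c("s_in", "s_down_edge") %in% hit))
  expect_false(any(c("s_down_out", "s_other_chr") %in% hit))

  # brute-force interval oracle on random fixtures
  set.seed(1)
  for (i in 1:10) {
    ann_r <- tibble::tibble(chrom = sample(1:2, 3, TRUE),
                            start = sample(1e6:2e6, 3),
                            gene_id = paste0("g", 1:3))
    ann_r$end <- ann_r$start + sample(1e4:1e5, 3)
    v_r <- tibble::tibble(snp_id = paste0("s", 1:40),
                          chrom = sample(1:2, 40, TRUE),
                          pos = sample(8e5:2.3e6, 40))
    oracle <- v_r$snp_id[sapply(seq_len(40), function(j) {
      any(v_r$chrom[j] == ann_r$chrom &
            v_r$pos[j] >= ann_r$start + 1 - 1e5 &
            v_r$pos[j] <= ann_r$end + 1e5)
    })]
    expect_setequal(map_snps_to_gene_windows(v_r, ann_r, ann_r$gene_id),
                    oracle)
  }
  expect_warning(map_snps_to_gene_windows(v, ann, c("gA", "nope")),
                 "unannotated")
})

test_that("LD clumping matches a brute-force application of the rule", {
  set.seed(2)
  # 5 variants: s1/s2 duplicates, s3 independent, s4/s5 correlated pair
  n <- 400
  base1 <- rbinom(n, 2, 0.3)
  base4 <- rbinom(n, 2, 0.4)
  ref <- cbind(s1 = base1, s2 = base1,
               s3 = rbinom(n, 2, 0.5),
               s4 = base4,
               s5 = ifelse(runif(n) < 0.95, base4, rbinom(n, 2, 0.4)))
  tab <- dplyr::bind_rows(
    gwas_row("s1", pos = 1.00e6, p = 1e-8),
    gwas_row("s2", pos = 1.01e6, p = 1e-4),
    gwas_row("s3", pos = 1.02e6, p = 1e-6),
    gwas_row("s4", pos = 1.03e6, p = 1e-3),
    gwas_row("s5", pos = 1.04e6, p = 1e-2)
  )
  out <- ld_clump(tab, ref)
  # brute force: iterate ascending p, drop if r2 > 0.1 with a kept variant
  # within 250 kb
  oracle <- local({
    ord <- order(tab$p)
    kept <- c()
    for (i in ord) {
      drop <- FALSE
      for (k in kept) {
        if (abs(tab$pos[k] - tab$pos[i]) <= 250000 &&
              cor(ref[, tab$snp_id[k]], ref[, tab$snp_id[i]])^2 > 0.1) {
          drop <- TRUE
        }
      }
      if (!drop) kept <- c(kept, i)
    }
    sort(tab$snp_id[kept])
  })
  expect_setequal(out$snp_id, oracle)
  expect_true("s1" %in% out$snp_id)   # p = 1e-8 copy wins
  expect_false("s2" %in% out$snp_id)  # duplicate discarded

  # r2 threshold 1 keeps everything (strict inequality)
  expect_equal(nrow(ld_clump(tab, ref, r2_threshold = 1)), 5)
  # zero window keeps everything
  expect_equal(nrow(ld_clump(tab, ref, window_kb = 0)), 5)
  expect_error(ld_clump(gwas_row("missing"), ref), "reference")
})

test_that("PRS scores: hand-computed sums, nesting, allele-flip invariance", {
  tab <- dplyr::bind_rows(
    gwas_row("v1", beta = 0.5, p = 1e-9),
    gwas_row("v2", pos = 2e6, beta = -0.3, p = 0.02),
    gwas_row("v3", pos = 3e6, beta = 0.2, p = 0.3)
  )
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1), 3, 3,
                dimnames = list(paste0("i", 1:3), c("v1", "v2", "v3")))
  thr <- c(1e-8, 0.05, 0.5)
  prs <- compute_prs(dos, tab, thresholds = thr)
  # single-SNP tier: scores are beta * dosage
  t1 <- prs[prs$threshold == 1e-8, ]
  expect_equal(t1$score, 0.5 * dos[, "v1"], ignore_attr = TRUE)
  expect_equal(unique(t1$n_snps), 1)
  # middle tier: v1 + v2 hand sum
  t2 <- prs[prs$threshold == 0.05, ]
  expect_equal(t2$score, 0.5 * dos[, "v1"] - 0.3 * dos[, "v2"],
               ignore_attr = TRUE)
  # nesting of counts
  counts <- unique(prs[, c("threshold", "n_snps")])$n_snps
  expect_identical(counts, c(1L, 2L, 3L))

  # zero betas give zero scores
  tab0 <- dplyr::mutate(tab, beta = 0)
  expect_true(all(compute_prs(dos, tab0, thresholds = thr)$score == 0))

  # allele-flip invariance: recode v2 with swapped alleles
  info_ok <- tibble::tibble(snp_id = c("v1", "v2", "v3"),
                            counted_allele = c("A", "G", "A"),
                            other_allele = c("G", "A", "G"))
  dos_flip <- dos
  dos_flip[, "v2"] <- 2 - dos[, "v2"]
  prs_flip <- compute_prs(dos_flip, tab, thresholds = thr,
                          dosage_info = info_ok)
  expect_equal(prs_flip$score, prs$score, tolerance = 1e-12)
})

test_that("parsed and complementary scores partition the clumped set", {
  set.seed(5)
  ann <- simulate_annotation(sprintf("gene%05d", 1:200), seed = 2)
  sim <- simulate_genotypes_and_gwas(
    geno_sim_params(n_snps = 600, n_gwas = 1500, n_target = 80, seed = 3),
    ann, sprintf("gene%05d", 1:20))
  cl <- ld_clump(snp_qc(sim$gwas), sim$dosages)
  full <- compute_prs(sim$dosages, cl, dosage_info = sim$dosage_info)
  both <- parse_prs(sim$dosages, cl, sprintf("gene%05d", 1:20), ann,
                    dosage_info = sim$dosage_info)
  wide <- dplyr::distinct(both, .data$threshold, .data$flavor,
                          .data$n_snps) |>
    tidyr::pivot_wider(names_from = "flavor", values_from = "n_snps") |>
    dplyr::left_join(dplyr::distinct(full, .data$threshold,
                                     full = .data$n_snps),
                     by = "threshold")
  expect_true(all(wide$parsed + wide$complementary == wide$full))
  expect_false(is.unsorted(wide$parsed))
  expect_false(is.unsorted(wide$complementary))

  # parsed + complementary scores add up to the full score
  tot <- dplyr::summarise(
    dplyr::group_by(both, .data$individual, .data$threshold),
    s = sum(.data$score), .groups = "drop")
  m <- dplyr::left_join(tot, full, by = c("individual", "threshold"))
  expect_equal(m$s, m$score, tolerance = 1e-10, ignore_attr = TRUE)

  # component set = all genes: complementary counts all zero
  all_g <- parse_prs(sim$dosages, cl, ann$gene_id, ann,
                     dosage_info = sim$dosage_info)
  expect_true(all(all_g$n_snps[all_g$flavor == "complementary"] == 0))
})

test_that("ancestry assignment separates two generative clusters", {
  set.seed(7)
  m <- 200
  maf_a <- runif(m, 0.1, 0.5)
  maf_b <- pmin(0.5, maf_a + runif(m, 0.1, 0.3))  # shifted frequencies
  draw <- function(n, maf) {
    sapply(maf, function(f) rbinom(n, 2, f))
  }
  ref <- rbind(draw(150, maf_a), draw(150, maf_b))
  colnames(ref) <- paste0("s", 1:m)
  labels <- rep(c(1, 0), each = 150)
  tgt_eur <- draw(60, maf_a); tgt_oth <- draw(60, maf_b)
  colnames(tgt_eur) <- colnames(tgt_oth) <- paste0("s", 1:m)
  res_e <- ancestry_assignment(tgt_eur, ref, labels, n_pcs = 10)
  res_o <- ancestry_assignment(tgt_oth, ref, labels, n_pcs = 10)
  expect_gte(mean(res_e$prob_european > 0.9), 0.95)
  expect_true(all(!res_o$keep))
  # zero threshold keeps everyone
  res0 <- ancestry_assignment(tgt_oth, ref, labels, n_pcs = 10,
                              prob_threshold = 0)
  expect_true(all(res0$keep))
})
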