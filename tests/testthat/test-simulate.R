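test_that("genotype simulation respects bounds, frequencies and seeds", {
  spec <- ld_block_spec(c(3, 3), c(0.8, 0.5), mafs = 0.3)
  g1 <- simulate_genotypes(spec, 500, seed = 42)
  g2 <- simulate_genotypes(spec, 500, seed = 42)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages >= 0 & g1$dosages <= 2))
  expect_setequal(unique(as.vector(g1$dosages)), c(0, 1, 2))

  # symmetry forces mean dosage 2*maf
  g_half <- simulate_genotypes(ld_block_spec(2, 0, mafs = 0.5), 50000,
                               seed = 7)
  expect_true(all(abs(colMeans(g_half$dosages) - 1) < 0.02))

  jit <- simulate_genotypes(spec, 100, seed = 1, imputation_noise_sd = 0.1)
  expect_true(all(jit$dosages >= 0 & jit$dosages <= 2))
  expect_false(all(jit$dosages %in% 0:2))
})

test_that("zero within-block correlation gives independent dosages", {
  g <- simulate_genotypes(ld_block_spec(6, 0, mafs = 0.3), 10000, seed = 3)
  cc <- cor(g$dosages)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.05))
})

test_that("block LD structure shows up in empirical dosage correlation", {
  g <- simulate_genotypes(ld_block_spec(c(5, 5), 0.8, mafs = 0.3), 5000,
                          seed = 4)
  cc <- cor(g$dosages)
  within <- cc[1:5, 1:5][upper.tri(diag(5))]
  across <- cc[1:5, 6:10]
  expect_gt(min(within), 0.4)
  expect_lt(max(abs(across)), 0.08)
})

test_that("invalid block specs are rejected with the offending block named", {
  expect_error(ld_block_spec(c(3, 3), c(0.5, 1)), "block 2")
  expect_error(ld_block_spec(3, 0, mafs = 0.7), "mafs")
})

test_that("splicing proportions follow the logistic link", {
  loc <- make_locus(n = 3000, effect = 2, noise_sd = 0, seed = 5)
  psi <- loc$ex$psi
  g <- loc$g$dosages[, 1]
  expect_equal(unique(psi[g == 0]), 0.5)
  expect_equal(unique(psi[g == 2]), stats::plogis(4))
  expect_true(all(psi > 0 & psi < 1))
})

test_that("a null effect with no noise gives constant psi", {
  loc <- make_locus(n = 50, effect = 0, noise_sd = 0, seed = 6)
  expect_equal(length(unique(loc$ex$psi)), 1L)
})

test_that("exon values equal the sum of containing transcripts at zero noise", {
  loc <- make_locus(n = 40, effect = 1, noise_sd = 0, seed = 7)
  ex <- loc$ex
  # E2 appears only in T1; E1 and E3 in both transcripts
  expect_equal(ex$exon[, "G1_E2"], ex$transcript[, "G1_T1"])
  expect_equal(ex$exon[, "G1_E1"], rowSums(ex$transcript))
  # skipping junction tracks the affected (E2-skipping) transcript T2
  expect_equal(ex$junction[, "J_G1_E1_G1_E3"], ex$transcript[, "G1_T2"])
  expect_true(all(tidy(ex)$value >= 0))
})

test_that("expression simulation is deterministic under a fixed seed", {
  a <- make_locus(seed = 8)$ex
  b <- make_locus(seed = 8)$ex
  expect_identical(a$exon, b$exon)
  expect_identical(a$junction_counts, b$junction_counts)
})

test_that("planted confounders surface in the leading expression factor", {
  loc0 <- make_locus(n = 150, effect = 0, noise_sd = 0.3, seed = 9)
  g <- loc0$g
  batch <- matrix(rep(c(-0.5, 0.5), each = 75))
  ex_conf <- simulate_expression(g, loc0$gm, loc0$truth, noise_sd = 0.3,
                                 confounders = batch,
                                 confounder_strength = 2, seed = 10)
  f_conf <- hidden_expression_factors(ex_conf$exon, 1)
  expect_gt(abs(cor(f_conf[, 1], batch[, 1])), 0.8)
  # without the confounder the leading factor is unrelated to the batch
  f_null <- hidden_expression_factors(loc0$ex$exon, 1)
  expect_lt(abs(cor(f_null[, 1], batch[, 1])), 0.3)
})

test_that("simulated z-scores match the stated MVN moments", {
  # null: 5000 draws on 4 independent SNPs
  z0 <- sapply(1:5000, function(i) {
    simulate_summary_stats(diag(4), 1, 0, seed = i)$z
  })
  expect_true(all(abs(rowMeans(z0)) < 0.05))
  expect_true(all(abs(apply(z0, 1, var) - 1) < 0.1))

  # identity LD, lambda = 5: only the causal mean is shifted
  z5 <- sapply(1:2000, function(i) {
    simulate_summary_stats(diag(4), 2, 5, seed = 10000 + i)$z
  })
  expect_lt(abs(mean(z5[2, ]) - 5), 0.08)
  expect_true(all(abs(rowMeans(z5[-2, , drop = FALSE])) < 0.08))

  # under LD the expected z decays with r
  spec <- ld_block_spec(c(4, 4), 0.8)
  zc <- sapply(1:2000, function(i) {
    simulate_summary_stats(spec, 1, 5, seed = 20000 + i)$z
  })
  expect_lt(abs(mean(zc[2, ]) - 5 * 0.8), 0.1)
  expect_lt(abs(mean(zc[5, ])), 0.1)
})

test_that("summary-stat simulation validates its inputs", {
  expect_error(simulate_summary_stats(diag(3), 4, 1), "out of range")
  bad <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(simulate_summary_stats(bad, 1, 0), "symmetric")
})

test_that("read tables are unthinned at unit mapping rates", {
  loc <- make_locus(n = 50, effect = 0, seed = 11)
  rt <- simulate_read_table(loc$g, loc$ex, "snp_001",
                            exonic_snp_pos = 2050, ref_mapping_rate = 1,
                            alt_mapping_rate = 1, seed = 12)
  expect_identical(attr(rt, "snp_feature"), "G1_E2")
  # with no thinning, counts are the raw Poisson draws: recounting with
  # an empty exclusion list must reproduce the table's own totals
  cnt <- recount_excluding_reads(rt, character(0))
  expect_equal(sum(cnt$n_reads), nrow(rt))
  # allele labels only occur on reads overlapping the exonic SNP
  expect_true(all(is.na(rt$allele) == is.na(rt$snp_id)))
})

test_that("alt-allele thinning halves retained alt reads at rate 0.5", {
  loc <- make_locus(n = 400, effect = 0, seed = 13, maf = 0.5)
  g <- loc$g
  g$dosages[, 1] <- 2  # every read that overlaps carries the alt allele
  ex <- simulate_expression(g, loc$gm, loc$truth, noise_sd = 0,
                            seed = 14)
  full <- simulate_read_table(g, ex, "snp_001", exonic_snp_pos = 2050,
                              ref_mapping_rate = 1, alt_mapping_rate = 1,
                              overlap_prob = 0.5, seed = 15)
  thin <- simulate_read_table(g, ex, "snp_001", exonic_snp_pos = 2050,
                              ref_mapping_rate = 1, alt_mapping_rate = 0.5,
                              overlap_prob = 0.5, seed = 15)
  n_full <- sum(full$allele == "alt", na.rm = TRUE)
  n_thin <- sum(thin$allele == "alt", na.rm = TRUE)
  expect_lt(abs(n_thin / n_full - 0.5), 0.05)
})

test_that("read simulation rejects bad rates and misplaced SNPs", {
  loc <- make_locus(n = 20, seed = 16)
  expect_error(simulate_read_table(loc$g, loc$ex, "snp_001",
                                   exonic_snp_pos = 2050,
                                   ref_mapping_rate = 0), "rates")
  expect_error(simulate_read_table(loc$g, loc$ex, "snp_001",
                                   exonic_snp_pos = 999999), "no feature")
})
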