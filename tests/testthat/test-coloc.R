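test_that("p-to-z conversion follows the signed two-sided convention", {
  expect_equal(z_from_p_and_beta(1, 3), 0)
  expect_equal(round(z_from_p_and_beta(0.0455, 2), 3), 2.000)
  expect_equal(z_from_p_and_beta(0.05, -1), -qnorm(0.975))
  expect_equal(round(z_from_p_and_beta(0.05, -1), 5), -1.95996)
  expect_error(z_from_p_and_beta(0, 1), "p must lie")
  # extreme p-values stay finite
  expect_true(is.finite(z_from_p_and_beta(1e-300, 1)))
})

test_that("single-SNP locus has the standard normal density at zero residual", {
  s <- summary_stats(z = 5, sigma = matrix(1),
                     meta = tibble::tibble(snp_id = "rs1"))
  ll <- causal_log_likelihoods(s, ridge = 0)
  expect_equal(unname(ll), -0.5 * log(2 * pi))
  expect_equal(unname(causal_posteriors(ll)$posterior), 1)
})

test_that("independent two-SNP example reproduces hand MVN algebra", {
  s <- summary_stats(z = c(3, 0), sigma = diag(2),
                     meta = tibble::tibble(snp_id = c("rs1", "rs2")))
  ll <- causal_log_likelihoods(s, ridge = 0)
  expect_equal(unname(ll[1] - ll[2]), 4.5)
  post <- causal_posteriors(ll)
  expect_equal(post$posterior[1], 1 / (1 + exp(-4.5)), tolerance = 1e-12)
  expect_equal(post$posterior[1], 0.989, tolerance = 1e-4)
})

test_that("likelihoods match a brute-force dense MVN oracle on small loci", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    sigma <- random_corr(n)
    z <- rnorm(n, 0, 2)
    s <- summary_stats(z, sigma,
                       meta = tibble::tibble(snp_id = sprintf("rs%d", 1:n)))
    ll <- causal_log_likelihoods(s, ridge = 0)
    oracle <- vapply(1:n, function(i) {
      mvn_logdens_oracle(z, z[i] * sigma[, i], sigma)
    }, numeric(1))
    expect_equal(unname(ll), oracle, tolerance = 1e-8)
    post <- causal_posteriors(ll)$posterior
    expect_equal(post, exp(oracle) / sum(exp(oracle)), tolerance = 1e-8)
  }
})

test_that("dropping the MVN constant leaves posteriors unchanged", {
  set.seed(52)
  sigma <- random_corr(6)
  s <- summary_stats(rnorm(6), sigma,
                     meta = tibble::tibble(snp_id = sprintf("rs%d", 1:6)))
  with_c <- causal_log_likelihoods(s, keep_constant = TRUE)
  without <- causal_log_likelihoods(s, keep_constant = FALSE)
  expect_equal(sd(with_c - without), 0, tolerance = 1e-12)
  expect_equal(causal_posteriors(with_c)$posterior,
               causal_posteriors(without)$posterior, tolerance = 1e-12)
  # log-sum-exp contract: any constant shift cancels
  expect_equal(causal_posteriors(with_c + 1234)$posterior,
               causal_posteriors(with_c)$posterior, tolerance = 1e-12)
})

test_that("posteriors normalize, permute consistently, and handle symmetry", {
  expect_equal(causal_posteriors(setNames(0, "a"))$posterior, 1)
  eq <- causal_posteriors(setNames(rep(-3.2, 4), paste0("s", 1:4)))
  expect_equal(eq$posterior, rep(0.25, 4))
  set.seed(53)
  ll <- setNames(rnorm(10), paste0("s", 1:10))
  perm <- sample(10)
  expect_equal(causal_posteriors(ll[perm])$posterior,
               causal_posteriors(ll)$posterior[perm])
  expect_equal(sum(causal_posteriors(ll)$posterior), 1, tolerance = 1e-12)
  expect_error(causal_posteriors(numeric(0)), "empty")
  expect_error(causal_posteriors(c(a = Inf)), "finite")
})

test_that("credible sets are minimal prefixes of the sorted posteriors", {
  p1 <- tibble::tibble(snp_id = "a", log_lik = 0, posterior = 1)
  cs1 <- credible_set(p1)
  expect_identical(cs1$snp_ids, "a")
  expect_equal(cs1$cumulative_probability, 1)

  p4 <- tibble::tibble(snp_id = c("a", "b", "c", "d"), log_lik = 0,
                       posterior = c(0.6, 0.3, 0.06, 0.04))
  cs4 <- credible_set(p4, 0.95)
  expect_identical(cs4$snp_ids, c("a", "b", "c"))
  expect_equal(cs4$cumulative_probability, 0.96)
  # brute force: no shorter prefix reaches the threshold
  expect_lt(sum(sort(p4$posterior, decreasing = TRUE)[1:2]), 0.95)

  cs0 <- credible_set(p4, 0)
  expect_length(cs0$snp_ids, 1)

  # ties broken by position, deterministically
  tied <- tibble::tibble(snp_id = c("far", "near"), log_lik = 0,
                         posterior = c(0.5, 0.5), pos = c(200, 100))
  expect_identical(credible_set(tied, 0.4)$snp_ids, "near")
})

test_that("overlap decisions follow the 0.05 cumulative rule", {
  post_a <- causal_posteriors(setNames(c(10, 0, -5), paste0("s", 1:3)))
  set_a <- credible_set(post_a)
  same <- credible_set_overlap(set_a, post_a)
  expect_identical(same$decision, "shared_not_excluded")
  expect_gte(same$other_trait_cumulative, 0.95)

  post_b <- causal_posteriors(setNames(c(-20, -20, 0), paste0("s", 1:3)))
  diff_ov <- credible_set_overlap(set_a, post_b)
  expect_identical(diff_ov$decision, "different_causal_variant")
  expect_lt(diff_ov$other_trait_cumulative, 0.05)
  td <- tidy(diff_ov)
  expect_identical(td$decision, "different_causal_variant")
  expect_equal(td$n_snps_total, 3L)

  post_other <- causal_posteriors(setNames(0, "elsewhere"))
  expect_error(credible_set_overlap(set_a, post_other), "merge")
})

test_that("SNP universes merge by intersection with allele harmonization", {
  meta3 <- function(ids, ea, oa) {
    tibble::tibble(snp_id = ids, pos = seq_along(ids),
                   effect_allele = ea, other_allele = oa)
  }
  a <- summary_stats(c(1, 2, 3), diag(3),
                     meta3(c("r1", "r2", "r3"), c("A", "C", "G"),
                           c("G", "T", "A")))
  # r2 has swapped effect/other alleles in trait b
  b <- summary_stats(c(1, 2, 3), diag(3),
                     meta3(c("r1", "r2", "r3"), c("A", "T", "G"),
                           c("G", "C", "A")))
  m <- merge_snp_universe(a, b)
  expect_equal(unname(m$b$z), c(1, -2, 3))
  expect_equal(unname(m$a$z), c(1, 2, 3))
  expect_identical(m$b$meta$effect_allele, m$a$meta$effect_allele)

  ident <- merge_snp_universe(a, a)
  expect_equal(unname(ident$b$z), unname(a$z))

  c_only <- summary_stats(1, matrix(1), meta3("zz", "A", "G"))
  expect_error(merge_snp_universe(a, c_only), "share no SNPs")

  mism <- summary_stats(c(1, 2, 3), diag(3),
                        meta3(c("r1", "r2", "r3"), c("A", "C", "T"),
                              c("G", "T", "C")))
  expect_error(merge_snp_universe(a, mism), "mismatch")
})

test_that("fine-mapping SNP filter applies MAF and INFO rules", {
  meta <- tibble::tibble(
    snp_id = c("rare", "low_info", "genotyped", "good"),
    maf = c(0.0005, 0.1, 0.2, 0.3),
    info = c(0.9, 0.4, NA, 0.8)
  )
  expect_setequal(finemap_snp_filter(meta), c("genotyped", "good"))
  # the maf column may carry major-allele frequencies
  meta2 <- tibble::tibble(snp_id = "flip", maf = 0.9995, info = NA)
  expect_length(finemap_snp_filter(meta2), 0)
})

test_that("LD ridge rescues perfect-LD pairs", {
  sigma <- matrix(c(1, 1, 1, 1), 2)  # rank deficient
  s <- summary_stats(c(2, 2), sigma,
                     meta = tibble::tibble(snp_id = c("r1", "r2")))
  expect_error(causal_log_likelihoods(s, ridge = 0))
  ll <- causal_log_likelihoods(s, ridge = 1e-6)
  expect_equal(unname(ll[1]), unname(ll[2]), tolerance = 1e-9)
  expect_equal(causal_posteriors(ll)$posterior, c(0.5, 0.5),
               tolerance = 1e-9)
})
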