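test_that("cis window selection follows gene distance and feature rules", {
  gm <- example_gene_model()   # gene G1 spans 1000-3300
  near <- cis_features(list(chr = "chr1", pos = 3300 + 499999), gm)
  expect_gt(nrow(near), 0)
  far <- cis_features(list(chr = "chr1", pos = 3300 + 500001), gm)
  expect_equal(nrow(far), 0)
  other_chr <- cis_features(list(chr = "chr2", pos = 2000), gm)
  expect_equal(nrow(other_chr), 0)

  feats <- cis_features(list(chr = "chr1", pos = 2000), gm)
  expect_setequal(unique(feats$feature_kind),
                  c("exon", "junction", "transcript"))

  # single-exon, single-transcript gene contributes no exon or transcript tests
  single <- gene_model(
    genes = tibble::tibble(gene_id = "S", chr = "chr1", start = 100,
                           end = 300),
    exons = tibble::tibble(exon_id = "S_E1", gene_id = "S", chr = "chr1",
                           start = 100, end = 300),
    transcripts = tibble::tibble(transcript_id = "S_T1", gene_id = "S",
                                 exon_id = "S_E1")
  )
  expect_equal(nrow(cis_features(list(chr = "chr1", pos = 200), single)), 0)
})

test_that("the exon model matches an independent lm() fit", {
  loc <- make_locus(n = 120, effect = 1, seed = 21)
  cov <- build_covariates(loc$g, loc$ex$exon, k = 2, m = 2)
  rec <- exon_association(loc$g$dosages[, 1], loc$ex$exon, 2, cov,
                          snp_id = "snp_001", gene_id = "G1")

  y <- rank_normalize(loc$ex$exon[, 2])
  loo <- rank_normalize(rowSums(loc$ex$exon[, -2]))
  df <- data.frame(y = y, g = loc$g$dosages[, 1], loo = loo,
                   cov$pcs, cov$factors)
  fit <- lm(y ~ g + loo + PC1 + PC2 + K1 + K2, data = df)
  sm <- summary(fit)$coefficients["g", ]
  expect_equal(rec$beta1, unname(sm["Estimate"]), tolerance = 1e-10)
  expect_equal(rec$se, unname(sm["Std. Error"]), tolerance = 1e-10)
  expect_equal(rec$p, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(rec$df, 120L - 7L)
  expect_identical(rec$feature_kind, "exon")
})

test_that("beta1 reduces to the marginal slope when covariates are orthogonalized out", {
  set.seed(22)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  covar <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  y <- 0.7 * g + rnorm(n)
  ex <- cbind(E1 = exp(y), E2 = exp(rnorm(n)))
  yr <- rank_normalize(y)
  loo <- rank_normalize(ex[, 2])
  # orthogonalize the covariates against the base design [1, g, loo]:
  # beta1 must then match the covariate-free normal-equations solution
  covar_o <- qr.resid(qr(cbind(1, g, loo)), covar)
  rec <- exon_association(g, ex, 1, covar_o)
  X0 <- cbind(1, g, loo)
  beta_oracle <- solve(crossprod(X0), crossprod(X0, yr))[2]
  expect_equal(rec$beta1, unname(beta_oracle), tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  loc <- make_locus(n = 40, seed = 23)
  expect_error(exon_association(rep(1, 40), loc$ex$exon, 1, NULL),
               "monomorphic")
  g <- loc$g$dosages[, 1]
  bad_cov <- cbind(a = g, b = g)   # collinear with g and each other
  expect_error(exon_association(g, loc$ex$exon, 1, bad_cov),
               "collinear")
  expect_error(exon_association(g[1:5], loc$ex$exon[1:5, ], 1,
                                matrix(rnorm(20), 5, 4)),
               "fewer samples")
  expect_error(exon_association(g, loc$ex$exon[, 1, drop = FALSE], 1, NULL),
               ">= 2 exons")
})

test_that("t-based p-values agree with a label-permutation null", {
  loc <- make_locus(n = 60, effect = 0.6, noise_sd = 0.4, seed = 24,
                    n_snps = 4)
  g <- loc$g$dosages[, 1]
  obs <- junction_association(g, loc$ex$junction[, 1], loc$ex$gene[, 1],
                              NULL)
  set.seed(25)
  n_perm <- 4000
  t_perm <- vapply(seq_len(n_perm), function(i) {
    junction_association(sample(g), loc$ex$junction[, 1],
                         loc$ex$gene[, 1], NULL)$statistic
  }, numeric(1))
  p_perm <- (1 + sum(abs(t_perm) >= abs(obs$statistic))) / (1 + n_perm)
  mc_sd <- sqrt(obs$p * (1 - obs$p) / n_perm)
  expect_lt(abs(p_perm - obs$p), 4 * mc_sd + 2 / n_perm)
})

test_that("junctions sharing a donor move in opposite directions", {
  loc <- make_locus(n = 300, effect = 1.5, seed = 26)
  g <- loc$g$dosages[, 1]
  gene_ab <- loc$ex$gene[, 1]
  # inclusion junction E1-E2 (transcript T1) vs skipping junction E1-E3 (T2)
  inc <- junction_association(g, loc$ex$junction[, "J_G1_E1_G1_E2"],
                              gene_ab, NULL)
  skp <- junction_association(g, loc$ex$junction[, "J_G1_E1_G1_E3"],
                              gene_ab, NULL)
  expect_lt(inc$p, 1e-4)
  expect_lt(skp$p, 1e-4)
  expect_lt(sign(inc$beta1) * sign(skp$beta1), 0)
})

test_that("rejection rate grows with the planted effect size", {
  rates <- vapply(c(0, 0.6, 1.5), function(eff) {
    hits <- vapply(1:80, function(i) {
      loc <- make_locus(n = 80, effect = eff, seed = 3000 + 17 * i,
                        n_snps = 2)
      transcript_association(loc$g$dosages[, 1],
                             loc$ex$transcript[, "G1_T2"],
                             loc$ex$gene[, 1], NULL)$p < 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[3], 0.8)
})

test_that("BH q-values match a hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.013), 0.013)
  set.seed(27)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_error(bh_fdr(c(0.1, 0)), "p_values")
})

test_that("transcript hits need directionally consistent exon/junction support", {
  loc <- make_locus(n = 300, effect = 1.5, seed = 28)
  cov <- build_covariates(loc$g, loc$ex$exon, 3, 3)
  sc <- sqtl_scan(loc$g, loc$ex, cov)
  out <- corroborate_transcript_hits(sc, loc$gm)
  hit_tx <- out[out$feature_kind == "transcript" & out$q < 0.05 &
                  out$snp_id == "snp_001", ]
  expect_true(all(!grepl("transcript_uncorroborated", hit_tx$flags)))

  # break the support: make every exon/junction p nominal-insignificant
  fake <- sc
  fake$p[fake$feature_kind != "transcript"] <- 0.5
  out2 <- corroborate_transcript_hits(fake, loc$gm)
  hit_tx2 <- out2[out2$feature_kind == "transcript" & out2$q < 0.05, ]
  expect_true(all(grepl("transcript_uncorroborated", hit_tx2$flags)))

  # support in the wrong direction does not rescue the hit: T2 contains
  # the skipping junction (must share sign) and excludes exon E2 (must
  # oppose); give both the wrong sign
  hand <- tibble::tibble(
    snp_id = "s", gene_id = "G1",
    feature_id = c("G1_T2", "J_G1_E1_G1_E3", "G1_E2"),
    feature_kind = c("transcript", "junction", "exon"),
    beta1 = c(1, -1, 1), se = 0.1, statistic = 10,
    p = c(1e-6, 1e-4, 1e-4), df = 100, n_samples = 110, flags = "",
    q = c(1e-5, 1e-3, 1e-3)
  )
  out3 <- corroborate_transcript_hits(hand, loc$gm)
  expect_match(out3$flags[1], "transcript_uncorroborated")
  # with consistent signs the same record is supported
  hand$beta1 <- c(1, 1, -1)
  out4 <- corroborate_transcript_hits(hand, loc$gm)
  expect_identical(out4$flags[1], "")

  # no transcript hits: untouched
  none <- sc[sc$feature_kind != "transcript", ]
  expect_identical(corroborate_transcript_hits(none, loc$gm), none)
})

test_that("paralog flagging marks listed genes and warns on unknown ids", {
  recs <- tibble::tibble(
    snp_id = "s", feature_id = c("a", "b"), feature_kind = "exon",
    gene_id = c("G1", "G2"), beta1 = 1, se = 1, statistic = 1, p = 0.5,
    df = 10, n_samples = 20, flags = ""
  )
  out <- flag_paralogs(recs, tibble::tibble(gene_id = "G1"))
  expect_equal(grepl("paralog_suspect", out$flags), c(TRUE, FALSE))
  expect_identical(flag_paralogs(recs, tibble::tibble(gene_id = character())),
                   recs)
  expect_warning(flag_paralogs(recs, tibble::tibble(gene_id = "NOPE")),
                 "absent")
})

test_that("per-family FDR treats exon, junction and transcript separately", {
  loc <- make_locus(n = 150, effect = 1, seed = 29, n_snps = 4)
  sc_fam <- sqtl_scan(loc$g, loc$ex, NULL, fdr_family = "per_kind")
  sc_pool <- sqtl_scan(loc$g, loc$ex, NULL, fdr_family = "pooled")
  for (kind in unique(sc_fam$feature_kind)) {
    sub <- sc_fam[sc_fam$feature_kind == kind, ]
    expect_equal(sub$q, bh_oracle(sub$p))
  }
  expect_equal(sc_pool$q, bh_oracle(sc_pool$p))
})
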