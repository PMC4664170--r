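# Simulation studies: the fixed synthetic conditions under which the
# pipeline's operating characteristics (coverage, discrimination, effect
# recovery, type-I error, confounder control, bias correction) are
# measured. Each study derives per-replicate seeds from its `seed` so runs
# are reproducible yet replicates independent.

derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Credible-set coverage under the single-causal-variant model
#'
#' Simulates loci of `n_snps` SNPs in LD blocks (correlation `r` within
#' blocks of `block_size`), plants one causal SNP per locus with
#' non-centrality `lambda`, fine-maps each locus, and reports how often
#' the credible set at `threshold` contains the planted SNP.
#'
#' @param n_loci number of simulated loci.
#' @param n_snps,block_size,r locus structure.
#' @param lambda causal non-centrality (expected causal z).
#' @param threshold credible-set threshold.
#' @param seed study seed.
#' @return list: `coverage` (fraction of loci whose set holds the causal
#'   SNP), `mean_set_size`, and the per-locus tibble `draws`.
#' @export
study_credible_coverage <- function(n_loci = 500, n_snps = 50,
                                    block_size = 10, r = 0.8, lambda = 5,
                                    threshold = 0.95, seed = 1) {
  spec <- ld_block_spec(rep(block_size, n_snps / block_size), r)
  seeds <- derive_seeds(seed, n_loci)
  causal <- with_local_seed(seed + 1L, sample.int(n_snps, n_loci, replace = TRUE))
  draws <- purrr::map_dfr(seq_len(n_loci), function(i) {
    ss <- simulate_summary_stats(spec, causal[i], lambda, seed = seeds[i])
    post <- finemap_locus(ss)
    cs <- credible_set(post, threshold)
    tibble(locus = i, causal_snp = ss$snp_ids[causal[i]],
           set_size = length(cs$snp_ids),
           covered = ss$snp_ids[causal[i]] %in% cs$snp_ids)
  })
  list(coverage = mean(draws$covered),
       mean_set_size = mean(draws$set_size), draws = draws)
}

#' Colocalization discrimination between shared and distinct causal SNPs
#'
#' Paired-trait draws on one locus: both traits get z-scores at
#' non-centrality `lambda`, either from the same causal SNP (`shared =
#' TRUE`) or from causal SNPs in different LD blocks (between-block
#' r-squared ~ 0). Trait A's credible set is intersected with trait B's
#' posteriors and the overlap decision recorded.
#'
#' @inheritParams study_credible_coverage
#' @param n_pairs number of paired draws.
#' @param shared same causal SNP for both traits?
#' @return list: `rate_shared_not_excluded`, `rate_different`, per-pair
#'   tibble `draws`.
#' @export
study_coloc_discrimination <- function(n_pairs = 200, shared = TRUE,
                                       n_snps = 50, block_size = 10,
                                       r = 0.8, lambda = 6, seed = 1) {
  spec <- ld_block_spec(rep(block_size, n_snps / block_size), r)
  c_a <- block_size %/% 2                      # mid-block, first block
  c_b <- if (shared) c_a else n_snps - block_size %/% 2  # last block
  seeds <- derive_seeds(seed, 2L * n_pairs)
  draws <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    sa <- simulate_summary_stats(spec, c_a, lambda, seed = seeds[2 * i - 1])
    sb <- simulate_summary_stats(spec, c_b, lambda, seed = seeds[2 * i])
    set_a <- credible_set(finemap_locus(sa))
    ov <- credible_set_overlap(set_a, finemap_locus(sb))
    tibble(pair = i, other_trait_cumulative = ov$other_trait_cumulative,
           decision = ov$decision)
  })
  list(rate_shared_not_excluded = mean(draws$decision == "shared_not_excluded"),
       rate_different = mean(draws$decision == "different_causal_variant"),
       draws = draws)
}

# one locus with a log-linear exon effect of known standardized slope:
# exon 1 is exp(c*g + e) so after rank normalization the regression slope
# on g is c / sd(c*g + e) = `slope`. The tested gene has `n_exons` exons;
# `n_panel_exons` further null exons emulate the transcriptome-wide panel
# the hidden expression factors are estimated from (factors fit to a
# handful of exons would absorb the tested exon's own signal).
slope_locus <- function(n, slope, maf, n_snps, n_exons, seed,
                        n_panel_exons = 500) {
  spec <- ld_block_spec(n_snps, 0, mafs = maf)
  g <- simulate_genotypes(spec, n, seed = seed)
  cc <- 0.5
  var_g <- 2 * maf * (1 - maf)
  s <- if (slope > 0) sqrt((cc / slope)^2 - cc^2 * var_g) else 1
  c_eff <- if (slope > 0) cc else 0
  with_local_seed(seed + 1L, {
    ex <- cbind(
      exp(c_eff * g$dosages[, 1] + rnorm(n, 0, s)),
      matrix(exp(rnorm(n * (n_exons - 1), 0, s)), n, n_exons - 1)
    )
    colnames(ex) <- paste0("E", seq_len(n_exons))
    rownames(ex) <- rownames(g$dosages)
    panel <- cbind(ex, matrix(exp(rnorm(n * n_panel_exons, 0, s)),
                              n, n_panel_exons))
    colnames(panel) <- c(colnames(ex), paste0("PX", seq_len(n_panel_exons)))
    list(genotypes = g, exon = ex, panel = panel)
  })
}

#' Recovery of a planted standardized exon effect
#'
#' Replicated loci where the tested exon's log expression is linear in
#' dosage with standardized slope `slope` (so the rank-normalized exon
#' regression should estimate `slope`), fitted with the full exon model
#' (leave-one-out gene covariate, 3 genotype PCs, 3 hidden factors).
#'
#' @param n_sims replicates.
#' @param n samples per replicate.
#' @param slope planted standardized effect per dosage unit.
#' @param maf allele frequency of the tested SNP.
#' @param n_snps SNPs in the covariate panel.
#' @param n_exons exons of the simulated gene.
#' @param seed study seed.
#' @return list: `mean_beta1`, `betas` (per-sim vector).
#' @export
study_effect_recovery <- function(n_sims = 200, n = 358, slope = 0.4,
                                  maf = 0.3, n_snps = 20, n_exons = 5,
                                  seed = 1) {
  seeds <- derive_seeds(seed, n_sims)
  betas <- vapply(seq_len(n_sims), function(i) {
    loc <- slope_locus(n, slope, maf, n_snps, n_exons, seeds[i])
    cov <- build_covariates(loc$genotypes, loc$panel, k = 3, m = 3)
    exon_association(loc$genotypes$dosages[, 1], loc$exon, 1, cov)$beta1
  }, numeric(1))
  list(mean_beta1 = mean(betas), betas = betas)
}

#' Type-I error of the exon test under the null
#'
#' One cohort, `n_tests` mutually independent null SNPs, each tested
#' against the same null exon with the full covariate model; reports the
#' rejection rate at `alpha`.
#'
#' @param n_tests number of null SNPs tested.
#' @param n samples.
#' @param alpha nominal level.
#' @param n_exons exons of the simulated gene.
#' @param seed study seed.
#' @return list: `rejection_rate`, `p` (vector of p-values).
#' @export
study_null_type1 <- function(n_tests = 2000, n = 358, alpha = 0.05,
                             n_exons = 5, seed = 1) {
  loc <- slope_locus(n, 0, 0.3, n_tests, n_exons, seed)
  cov <- build_covariates(loc$genotypes, loc$panel, k = 3, m = 3)
  p <- vapply(seq_len(n_tests), function(j) {
    exon_association(loc$genotypes$dosages[, j], loc$exon, 1, cov)$p
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p = p)
}

#' Confounder control: planted ancestry, inflation, and PC rescue
#'
#' Two equally sized populations with allele frequencies divergent by
#' `divergence` at every SNP; population membership also shifts
#' log-expression (`strength` on the log scale via the confounder
#' loadings). Every SNP is a null for splicing but correlated with
#' ancestry, so the unadjusted exon test inflates; the genomic inflation
#' factor lambda_GC (median chi-square over its null median) quantifies
#' it, and adding the leading genotype PCs should restore nominal
#' type-I error.
#'
#' @param n_per_pop samples per population.
#' @param n_snps number of null SNPs tested (and in the PCA panel).
#' @param n_genes genes the tests rotate over; each gene draws its own
#'   confounder loadings, so the inflation estimate averages over genes
#'   rather than reflecting a single gene's loading draw.
#' @param divergence allele-frequency difference between populations.
#' @param strength confounder strength on log-expression.
#' @param k_pcs PCs used in the adjusted test.
#' @param alpha nominal level.
#' @param seed study seed.
#' @return list: `lambda_gc_unadjusted`, `rejection_rate_adjusted`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
study_confounding <- function(n_per_pop = 200, n_snps = 2000,
                              n_genes = 10, divergence = 0.2,
                              strength = 2, k_pcs = 3, alpha = 0.05,
                              seed = 1) {
  maf_a <- with_local_seed(seed, stats::runif(n_snps, 0.1, 0.5 - divergence))
  g_a <- simulate_genotypes(ld_block_spec(n_snps, 0, mafs = maf_a),
                            n_per_pop, seed = seed + 1L)
  g_b <- simulate_genotypes(ld_block_spec(n_snps, 0, mafs = maf_a + divergence),
                            n_per_pop, seed = seed + 2L)
  dos <- rbind(g_a$dosages, g_b$dosages)
  rownames(dos) <- sprintf("S%04d", seq_len(2 * n_per_pop))
  geno <- structure(list(dosages = dos, snp_info = g_a$snp_info),
                    class = "genotype_matrix")
  pop <- rep(c(-0.5, 0.5), each = n_per_pop)

  gm <- example_gene_model()
  truth <- splice_effect_truth(1, 0, 0, "G1_T2", "G1")
  exons <- lapply(seq_len(n_genes), function(k) {
    simulate_expression(geno, gm, truth, noise_sd = 0.3,
                        confounders = matrix(pop),
                        confounder_strength = strength,
                        seed = seed + 2L + k)$exon
  })
  pcs <- genotype_pca(geno, k_pcs)
  fits <- purrr::map_dfr(seq_len(n_snps), function(j) {
    g <- dos[, j]
    ex_j <- exons[[(j - 1L) %% n_genes + 1L]]
    tibble(
      p_raw = exon_association(g, ex_j, 2, NULL)$p,
      p_adj = exon_association(g, ex_j, 2, pcs)$p
    )
  })
  chi <- qchisq(fits$p_raw, df = 1, lower.tail = FALSE)
  list(
    lambda_gc_unadjusted = median(chi) / qchisq(0.5, df = 1),
    rejection_rate_adjusted = mean(fits$p_adj < alpha),
    p_unadjusted = fits$p_raw, p_adjusted = fits$p_adj
  )
}

#' Mapping-bias false positives and their correction
#'
#' The headline bias experiment: splicing is null, but an exonic SNP in
#' perfect LD with the tested SNP sits inside the tested exon and reads
#' carrying its alternate allele map at rate `alt_rate` versus `ref_rate`
#' for the reference allele. The naive test on raw feature counts picks
#' up the spurious association; recounting after excluding reads across
#' LD SNPs (r-squared > `r2_threshold`) should restore nominal type-I
#' error.
#'
#' @param n_sims replicates.
#' @param n samples.
#' @param ref_rate,alt_rate allele-specific read retention rates.
#' @param maf allele frequency of the SNP pair.
#' @param reads_per_unit,overlap_prob read-simulation depth and the
#'   chance a read of the exon covers the SNP.
#' @param r2_threshold LD cut for the audit.
#' @param alpha nominal level.
#' @param seed study seed.
#' @return list: `naive_rejection_rate`, `filtered_rejection_rate`,
#'   per-sim tibble `draws` (p_naive, p_filtered).
#' @export
study_mapping_bias <- function(n_sims = 200, n = 300, ref_rate = 1,
                               alt_rate = 0.8, maf = 0.3,
                               reads_per_unit = 1.2, overlap_prob = 0.6,
                               r2_threshold = 0.1, alpha = 0.05, seed = 1) {
  gm <- example_gene_model()
  # index SNP away from the gene, its perfect-LD partner inside exon E2
  spec <- ld_block_spec(2, 0, mafs = maf, positions = c(50000, 2050))
  seeds <- derive_seeds(seed, n_sims)
  draws <- purrr::map_dfr(seq_len(n_sims), function(i) {
    g <- simulate_genotypes(spec, n, seed = seeds[i])
    g$dosages[, 2] <- g$dosages[, 1]
    truth <- splice_effect_truth(1, 0, 0, "G1_T2", "G1")
    ex <- simulate_expression(g, gm, truth, noise_sd = 0.2,
                              seed = seeds[i] + 1L)
    rt <- simulate_read_table(g, ex, "snp_002",
                              ref_mapping_rate = ref_rate,
                              alt_mapping_rate = alt_rate,
                              reads_per_unit = reads_per_unit,
                              overlap_prob = overlap_prob,
                              features = "G1_E2", seed = seeds[i] + 2L)
    samples <- rownames(g$dosages)
    naive <- counts_matrix(recount_excluding_reads(rt, character(0),
                                                   samples = samples))
    hits <- ld_snps_in_feature("snp_001", feature_intervals(gm, "G1_E2"),
                               ld_from_dosages(g), g$snp_info, r2_threshold)
    filt <- counts_matrix(recount_excluding_reads(rt, hits,
                                                  samples = samples))
    g1 <- g$dosages[, 1]
    tibble(
      sim = i,
      p_naive = retest_filtered(g1, naive[samples, "G1_E2"],
                                ex$gene[, 1], NULL)$p,
      p_filtered = retest_filtered(g1, filt[samples, "G1_E2"],
                                   ex$gene[, 1], NULL)$p
    )
  })
  list(naive_rejection_rate = mean(draws$p_naive < alpha),
       filtered_rejection_rate = mean(draws$p_filtered < alpha),
       draws = draws)
}
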