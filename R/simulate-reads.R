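#' Simulate an allele-tagged read table with reference mapping bias
#'
#' A desk-scale stand-in for aligned RNA-seq reads. Per sample and feature
#' (exons and junctions of the gene model), read counts are Poisson around
#' `reads_per_unit` times the feature's expression value. Reads in the
#' feature containing `exonic_snp_id` overlap that SNP with probability
#' `overlap_prob`; an overlapping read carries the alternate allele with
#' probability dosage/2 and is retained with probability
#' `ref_mapping_rate` or `alt_mapping_rate` according to the allele it
#' carries — aligners place reads carrying the reference allele more
#' readily, and unequal rates reproduce that bias. Non-overlapping reads
#' are always retained.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression an `expression_set` over the same samples.
#' @param exonic_snp_id SNP whose position falls inside one exon of the
#'   gene model. If absent from `genotypes`, its genotype is synthesized
#'   in LD `ld_with_causal` with the causal SNP of `expression$truth`
#'   (`ld_with_causal = 1` gives perfect LD).
#' @param ld_with_causal LD correlation r used only when the exonic SNP is
#'   not in the genotype panel.
#' @param ref_mapping_rate,alt_mapping_rate retention probabilities in
#'   `(0, 1]` for reads carrying the reference / alternate allele.
#' @param exonic_snp_pos position of the exonic SNP; defaults to its
#'   `snp_info` entry when in the panel, otherwise required.
#' @param reads_per_unit expected reads per expression unit.
#' @param overlap_prob probability a read of the SNP's feature covers the
#'   SNP position.
#' @param features which features to generate reads for (default: every
#'   exon and junction of the gene model).
#' @param seed integer seed.
#' @return tibble of retained (mapped) reads with columns `sample_id`,
#'   `feature_id`, `read_id`, `snp_id` (NA when the read does not overlap
#'   the SNP) and `allele` ("ref"/"alt"/NA). The feature holding the SNP
#'   is recorded in attribute `snp_feature`.
#' @export
simulate_read_table <- function(genotypes, expression, exonic_snp_id,
                                ld_with_causal = 1,
                                ref_mapping_rate = 1, alt_mapping_rate = 1,
                                exonic_snp_pos = NULL,
                                reads_per_unit = 0.5, overlap_prob = 0.5,
                                features = NULL, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_set"))
  if (ref_mapping_rate <= 0 || ref_mapping_rate > 1 ||
      alt_mapping_rate <= 0 || alt_mapping_rate > 1) {
    stop("mapping rates must lie in (0, 1]", call. = FALSE)
  }
  gm <- expression$gene_model
  n <- nrow(genotypes$dosages)

  in_panel <- exonic_snp_id %in% genotypes$snp_info$snp_id
  if (is.null(exonic_snp_pos)) {
    if (!in_panel) stop("exonic_snp_pos required for a SNP outside the panel",
                        call. = FALSE)
    exonic_snp_pos <- genotypes$snp_info$pos[
      genotypes$snp_info$snp_id == exonic_snp_id]
  }
  # locate the feature whose interval(s) contain the SNP position
  feats <- c(gm$exons$exon_id, gm$junctions$junction_id)
  snp_feature <- NULL
  for (f in feats) {
    iv <- feature_intervals(gm, f)
    if (any(exonic_snp_pos >= iv$start & exonic_snp_pos < iv$end)) {
      snp_feature <- f
      break
    }
  }
  if (is.null(snp_feature)) {
    stop("exonic SNP at position ", exonic_snp_pos,
         " lies inside no feature of the gene model", call. = FALSE)
  }

  with_local_seed(seed, {
    g_snp <- if (in_panel) {
      genotypes$dosages[, exonic_snp_id]
    } else {
      g_causal <- genotypes$dosages[, expression$truth$causal_snp_index]
      if (abs(ld_with_causal) >= 1) {
        g_causal
      } else {
        # haplotype-level recombination toward the target correlation
        p <- mean(g_causal) / 2
        swap <- 1 - abs(ld_with_causal)
        h <- cbind(rbinom(n, 1, p), rbinom(n, 1, p))
        keep1 <- rbinom(n, 1, 1 - swap)
        keep2 <- rbinom(n, 1, 1 - swap)
        half <- function(g) pmin(g, 1)  # crude haplotype split of a dosage
        keep1 * half(g_causal) + (1 - keep1) * h[, 1] +
          keep2 * pmax(g_causal - 1, 0) + (1 - keep2) * h[, 2]
      }
    }
    p_alt <- pmin(pmax(g_snp / 2, 0), 1)

    values <- cbind(expression$exon, expression$junction)
    if (!is.null(features)) {
      stopifnot(all(features %in% colnames(values)))
      values <- values[, features, drop = FALSE]
    }
    samples <- rownames(genotypes$dosages)
    per <- purrr::map_dfr(colnames(values), function(f) {
      n_reads <- rpois(n, reads_per_unit * values[, f])
      if (f == snp_feature) {
        n_over <- rbinom(n, n_reads, overlap_prob)
        n_alt <- rbinom(n, n_over, p_alt)
        n_ref <- n_over - n_alt
        keep_ref <- rbinom(n, n_ref, ref_mapping_rate)
        keep_alt <- rbinom(n, n_alt, alt_mapping_rate)
        n_non <- n_reads - n_over
        tibble(
          sample_id = rep(samples, n_non + keep_ref + keep_alt),
          feature_id = f,
          snp_id = rep(rep(c(NA_character_, exonic_snp_id, exonic_snp_id),
                           times = n),
                       times = as.vector(rbind(n_non, keep_ref, keep_alt))),
          allele = rep(rep(c(NA_character_, "ref", "alt"), times = n),
                       times = as.vector(rbind(n_non, keep_ref, keep_alt)))
        )
      } else {
        tibble(sample_id = rep(samples, n_reads), feature_id = f,
               snp_id = NA_character_, allele = NA_character_)
      }
    })
    per %>%
      mutate(read_id = sprintf("r%07d", row_number()), .after = "feature_id") %>%
      structure(snp_feature = snp_feature, exonic_dosage = g_snp)
  })
}
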