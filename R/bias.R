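#' LD SNPs lying inside an associated feature
#'
#' Finds the SNPs in LD with the index SNP (squared correlation above
#' `r2_threshold`) whose position falls inside the tested feature — for a
#' junction, inside either exonic flank a junction-spanning read covers.
#' Reads crossing such SNPs are the ones vulnerable to reference mapping
#' bias.
#'
#' @param index_snp id of the index (risk-associated) SNP.
#' @param feature tibble of intervals from [feature_intervals()] (columns
#'   `chr`, `start`, `end`, 0-based half-open).
#' @param ld_source tibble with columns `snp_a`, `snp_b`, `r2`; treated as
#'   symmetric. [ld_from_dosages()] produces one.
#' @param snp_positions tibble with columns `snp_id`, `chr`, `pos`.
#' @param r2_threshold LD cut; SNPs strictly above it are candidates.
#' @return character vector of SNP ids (the index SNP itself is included
#'   when it lies inside the feature).
#' @export
ld_snps_in_feature <- function(index_snp, feature, ld_source, snp_positions,
                               r2_threshold = 0.1) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  partners <- bind_rows(
    ld_source %>% filter(.data$snp_a == index_snp) %>%
      select(snp_id = "snp_b", "r2"),
    ld_source %>% filter(.data$snp_b == index_snp) %>%
      select(snp_id = "snp_a", "r2")
  ) %>%
    bind_rows(tibble(snp_id = index_snp, r2 = 1)) %>%
    group_by(.data$snp_id) %>% summarise(r2 = max(.data$r2)) %>%
    filter(.data$r2 > r2_threshold)
  cand <- snp_positions %>% semi_join(partners, by = "snp_id")
  inside <- purrr::map_lgl(seq_len(nrow(cand)), function(i) {
    any(cand$chr[i] == feature$chr &
          cand$pos[i] >= feature$start & cand$pos[i] < feature$end)
  })
  sort(cand$snp_id[inside])
}

#' Recount feature coverage excluding reads that map across given SNPs
#'
#' @param read_table tibble from [simulate_read_table()] (or equivalent)
#'   with columns `sample_id`, `feature_id`, `snp_id`.
#' @param snp_ids SNPs whose overlapping reads are dropped.
#' @param samples optional sample universe so samples with zero retained
#'   reads still appear as zero counts.
#' @return tibble `sample_id` x `feature_id` with `n_reads` after
#'   exclusion (wide matrix available via [counts_matrix()]).
#' @export
recount_excluding_reads <- function(read_table, snp_ids, samples = NULL) {
  kept <- read_table %>%
    filter(is.na(.data$snp_id) | !(.data$snp_id %in% snp_ids)) %>%
    count(.data$sample_id, .data$feature_id, name = "n_reads")
  samples <- samples %||% sort(unique(read_table$sample_id))
  tidyr::complete(
    kept,
    sample_id = samples,
    feature_id = sort(unique(read_table$feature_id)),
    fill = list(n_reads = 0L)
  )
}

#' Long read counts to a samples x features matrix
#'
#' @param counts tibble with `sample_id`, `feature_id`, `n_reads`.
#' @return numeric matrix with samples as rows.
#' @export
counts_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(counts, id_cols = "sample_id",
                             names_from = "feature_id",
                             values_from = "n_reads", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' Re-test an association on bias-filtered counts
#'
#' After dropping reads that map across LD SNPs, the association with the
#' index SNP is recalculated adjusting for overall gene expression and
#' genetic ancestry only (no hidden expression factors).
#'
#' @param g dosage vector.
#' @param filtered_counts per-sample read counts of the feature after
#'   exclusion.
#' @param gene_abundance per-sample gene abundance.
#' @param pcs samples x k matrix of genotype principal components (or a
#'   `covariate_set`, of which only the PCs are used).
#' @param ... identifiers passed to the fit (`snp_id`, `feature_id`,
#'   `gene_id`).
#' @return one-row association tibble.
#' @export
retest_filtered <- function(g, filtered_counts, gene_abundance, pcs = NULL,
                            ...) {
  if (inherits(pcs, "covariate_set")) pcs <- pcs$pcs
  if (var(filtered_counts) == 0) {
    stop("filtered counts are constant; nothing left to test", call. = FALSE)
  }
  fit_assoc(rank_normalize(filtered_counts), g,
            rank_normalize(gene_abundance), pcs, ...)
}

#' Audit an association for allelic mapping bias
#'
#' Bundles the three audit steps: find LD SNPs inside the associated
#' feature, recount its reads excluding those SNPs, and re-test against
#' the index SNP. The association is declared `mapping_bias_suspect` when
#' it was significant before (q < `fdr_threshold`) but loses even nominal
#' significance after filtering (p >= `alpha_after`).
#'
#' @param record one-row association tibble (needs `snp_id`, `feature_id`,
#'   `gene_id`, `q`).
#' @param genotypes a `genotype_matrix` holding the index SNP.
#' @param expression the `expression_set` (for gene abundance and model).
#' @param read_table allele-tagged reads covering the feature.
#' @param pcs ancestry PCs (see [retest_filtered()]).
#' @param ld_source LD table; defaults to [ld_from_dosages()] of the
#'   panel.
#' @param snp_positions SNP position table; defaults to the panel's
#'   `snp_info`. Supply both when auditing SNPs outside the panel.
#' @param r2_threshold LD cut (default 0.1).
#' @param fdr_threshold,alpha_after before/after significance thresholds.
#' @return tibble with the original record plus `ld_snps_in_feature`
#'   (count), `p_filtered`, `beta1_filtered` and updated `flags`.
#' @export
audit_mapping_bias <- function(record, genotypes, expression, read_table,
                               pcs = NULL, ld_source = NULL,
                               snp_positions = NULL, r2_threshold = 0.1,
                               fdr_threshold = 0.05, alpha_after = 0.05) {
  ld_source <- ld_source %||% ld_from_dosages(genotypes)
  snp_positions <- snp_positions %||% genotypes$snp_info
  extra <- attr(read_table, "extra_snp_positions")
  if (!is.null(extra)) snp_positions <- bind_rows(snp_positions, extra)
  iv <- feature_intervals(expression$gene_model, record$feature_id)
  hits <- ld_snps_in_feature(record$snp_id, iv, ld_source, snp_positions,
                             r2_threshold)
  counts <- recount_excluding_reads(read_table, hits,
                                    samples = rownames(genotypes$dosages))
  cm <- counts_matrix(counts)
  refit <- retest_filtered(
    genotypes$dosages[, record$snp_id],
    cm[rownames(genotypes$dosages), record$feature_id],
    expression$gene[, record$gene_id], pcs,
    snp_id = record$snp_id, feature_id = record$feature_id,
    gene_id = record$gene_id
  )
  suspect <- record$q < fdr_threshold && refit$p >= alpha_after
  record %>%
    mutate(
      n_ld_snps_in_feature = length(hits),
      beta1_filtered = refit$beta1,
      p_filtered = refit$p,
      flags = add_flag(.data$flags, "mapping_bias_suspect", suspect)
    )
}
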