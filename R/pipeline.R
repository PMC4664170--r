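#' Per-SNP splicing summary statistics for one feature
#'
#' Fine-mapping a splicing signal needs a z-score for every SNP at the
#' locus against the same feature. Each polymorphic panel SNP is run
#' through the association model matching the feature's kind; z-scores
#' come from the two-sided p-values signed by the fitted coefficients, and
#' the LD matrix is the dosage correlation of the panel.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression an `expression_set`.
#' @param feature_id,feature_kind the feature to score.
#' @param covariates a `covariate_set` or NULL.
#' @param snp_ids SNPs to score (default: whole panel; monomorphic SNPs
#'   are skipped with a warning).
#' @return a `summary_stats` object over the scored SNPs.
#' @export
splicing_summary_stats <- function(genotypes, expression, feature_id,
                                   feature_kind, covariates = NULL,
                                   snp_ids = NULL) {
  snp_ids <- snp_ids %||% genotypes$snp_info$snp_id
  poly <- snp_ids[apply(genotypes$dosages[, snp_ids, drop = FALSE], 2,
                        function(v) var(v) > 0)]
  if (length(poly) < length(snp_ids)) {
    warning(length(snp_ids) - length(poly),
            " monomorphic SNP(s) skipped in the splicing scan")
  }
  gm <- expression$gene_model
  gene_id <- if (feature_kind == "exon") {
    gm$exons$gene_id[gm$exons$exon_id == feature_id]
  } else if (feature_kind == "junction") {
    gm$junctions$gene_id[gm$junctions$junction_id == feature_id]
  } else {
    unique(gm$transcripts$gene_id[gm$transcripts$transcript_id == feature_id])
  }
  recs <- purrr::map_dfr(poly, function(sid) {
    g <- genotypes$dosages[, sid]
    switch(
      feature_kind,
      exon = {
        ex_ids <- gm$exons$exon_id[gm$exons$gene_id == gene_id]
        exon_association(g, expression$exon[, ex_ids, drop = FALSE],
                         which(ex_ids == feature_id), covariates,
                         snp_id = sid, gene_id = gene_id)
      },
      junction = junction_association(
        g, expression$junction[, feature_id], expression$gene[, gene_id],
        covariates, snp_id = sid, feature_id = feature_id,
        gene_id = gene_id),
      transcript = transcript_association(
        g, expression$transcript[, feature_id], expression$gene[, gene_id],
        covariates, snp_id = sid, feature_id = feature_id,
        gene_id = gene_id)
    )
  })
  z <- z_from_p_and_beta(recs$p, recs$beta1)
  sigma <- cor(genotypes$dosages[, poly, drop = FALSE])
  meta <- genotypes$snp_info %>% filter(.data$snp_id %in% poly)
  summary_stats(z[match(meta$snp_id, recs$snp_id)],
                sigma[meta$snp_id, meta$snp_id], meta)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one place with the
#' study defaults: +-500 kb cis window, FDR 0.05, 3 genotype PCs, 3 hidden
#' factors, LD r-squared 0.1 for the bias audit, 0.95 credible sets with
#' the 0.05 exclusion rule, and a 1e-6 LD ridge.
#'
#' @param window,fdr_threshold,pcs_k,factors_m,bias_r2,credible_threshold,
#'   exclusion_threshold,ridge,fdr_family,max_zero_fraction see module
#'   functions.
#' @param seed integer seed recorded in the run log.
#' @return a `sqtl_config` list.
#' @export
sqtl_config <- function(window = 500000, fdr_threshold = 0.05, pcs_k = 3,
                        factors_m = 3, bias_r2 = 0.1,
                        credible_threshold = 0.95,
                        exclusion_threshold = 0.05, ridge = 1e-6,
                        fdr_family = "per_kind", max_zero_fraction = 0.25,
                        seed = NULL) {
  stopifnot(window > 0, fdr_threshold > 0, fdr_threshold < 1,
            bias_r2 >= 0, bias_r2 <= 1,
            credible_threshold > 0, credible_threshold <= 1,
            exclusion_threshold > 0, exclusion_threshold < 1)
  structure(as.list(environment()), class = "sqtl_config")
}

#' Run the splicing-QTL discovery and colocalization pipeline
#'
#' End-to-end orchestration: covariate construction, the cis association
#' scan with per-family FDR, transcript corroboration and paralog
#' flagging, the mapping-bias audit of significant exon/junction hits
#' (when a read table is supplied), and — when GWAS summary statistics
#' are supplied — single-causal-variant fine-mapping of both traits on
#' the merged SNP universe, the GWAS credible set, and the overlap
#' decision for the locus's most significant splicing feature.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression an `expression_set` on the same samples.
#' @param gwas optional `summary_stats` for the disease trait.
#' @param read_table optional allele-tagged read table for the bias audit.
#' @param paralog_table optional tibble of genes with homolog loci.
#' @param config a [sqtl_config()].
#' @param out_dir optional directory; when given, the association table,
#'   audit table, overlap report and run log are written there as
#'   TSV/JSON.
#' @return object of class `sqtl_report`: list with `associations`,
#'   `audit`, `covariates`, `splicing_posteriors`, `gwas_posteriors`,
#'   `overlap`, `log`.
#' @export
run_sqtl_pipeline <- function(genotypes, expression, gwas = NULL,
                              read_table = NULL, paralog_table = NULL,
                              config = sqtl_config(), out_dir = NULL) {
  log <- list(
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("splicecoloc")),
    seed = config$seed,
    thresholds = config[c("window", "fdr_threshold", "pcs_k", "factors_m",
                          "bias_r2", "credible_threshold",
                          "exclusion_threshold", "ridge")],
    exclusions = list()
  )

  covariates <- build_covariates(genotypes, expression$exon,
                                 k = config$pcs_k, m = config$factors_m)
  assoc <- sqtl_scan(genotypes, expression, covariates,
                     window = config$window, fdr_family = config$fdr_family,
                     max_zero_fraction = config$max_zero_fraction)
  if (nrow(assoc) == 0) stop("sqtl_assoc stage produced no tests", call. = FALSE)
  assoc <- corroborate_transcript_hits(assoc, expression$gene_model,
                                       fdr_threshold = config$fdr_threshold)
  assoc <- flag_paralogs(assoc, paralog_table)

  audit <- NULL
  if (!is.null(read_table)) {
    to_audit <- assoc %>%
      filter(.data$q < config$fdr_threshold,
             .data$feature_kind %in% c("exon", "junction"),
             .data$feature_id %in% unique(read_table$feature_id))
    audit <- purrr::map_dfr(seq_len(nrow(to_audit)), function(i) {
      audit_mapping_bias(to_audit[i, ], genotypes, expression, read_table,
                         pcs = covariates, r2_threshold = config$bias_r2,
                         fdr_threshold = config$fdr_threshold)
    })
    if (!is.null(audit) && nrow(audit) > 0) {
      biased <- audit %>% filter(grepl("mapping_bias_suspect", .data$flags))
      for (i in seq_len(nrow(biased))) {
        key <- assoc$snp_id == biased$snp_id[i] &
          assoc$feature_id == biased$feature_id[i]
        assoc$flags[key] <- add_flag(assoc$flags[key],
                                     "mapping_bias_suspect", TRUE)
      }
    }
  }
  for (flag in c("transcript_uncorroborated", "paralog_suspect",
                 "mapping_bias_suspect")) {
    hit <- assoc %>% filter(grepl(flag, .data$flags, fixed = TRUE))
    if (nrow(hit) > 0) {
      log$exclusions[[flag]] <- paste(hit$snp_id, hit$feature_id, sep = ":")
    }
  }

  spl_post <- gwas_post <- overlap <- NULL
  if (!is.null(gwas)) {
    clean <- assoc %>% filter(.data$flags == "")
    best <- clean %>% arrange(.data$p) %>% head(1)
    if (nrow(best) == 1) {
      keep <- finemap_snp_filter(genotypes$snp_info)
      spl_stats <- splicing_summary_stats(
        genotypes, expression, best$feature_id, best$feature_kind,
        covariates, snp_ids = keep)
      merged <- merge_snp_universe(gwas, spl_stats)
      gwas_post <- finemap_locus(merged$a, ridge = config$ridge)
      spl_post <- finemap_locus(merged$b, ridge = config$ridge)
      gwas_set <- credible_set(gwas_post, config$credible_threshold)
      overlap <- credible_set_overlap(gwas_set, spl_post,
                                      config$exclusion_threshold)
      log$coloc_feature <- best$feature_id
    }
  }

  report <- structure(
    list(associations = assoc, audit = audit, covariates = covariates,
         splicing_posteriors = spl_post, gwas_posteriors = gwas_post,
         overlap = overlap, log = log),
    class = "sqtl_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.sqtl_report <- function(x, ...) {
  cat("<sqtl_report> ", nrow(x$associations), " association tests; ",
      sum(x$associations$q < 0.05), " at q < 0.05\n", sep = "")
  if (!is.null(x$overlap)) {
    cat("  coloc decision: ", x$overlap$decision, " (other-trait cumulative ",
        signif(x$overlap$other_trait_cumulative, 3), ")\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$associations, file.path(out_dir, "associations.tsv"))
  if (!is.null(report$audit) && nrow(report$audit) > 0) {
    readr::write_tsv(report$audit, file.path(out_dir, "bias_audit.tsv"))
  }
  if (!is.null(report$overlap)) {
    jsonlite::write_json(
      c(as.list(tidy(report$overlap)),
        list(credible_set = report$overlap$set$snp_ids)),
      file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
    readr::write_tsv(as_tibble(report$splicing_posteriors),
                     file.path(out_dir, "splicing_posteriors.tsv"))
    readr::write_tsv(as_tibble(report$gwas_posteriors),
                     file.path(out_dir, "gwas_posteriors.tsv"))
  }
  jsonlite::write_json(report$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @describeIn run_sqtl_pipeline association table of a report.
#' @param x an `sqtl_report`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.sqtl_report <- function(x, ...) as_tibble(x$associations)

#' @describeIn run_sqtl_pipeline one-row run summary.
#' @exportS3Method generics::glance
glance.sqtl_report <- function(x, ...) {
  tibble(
    n_tests = nrow(x$associations),
    n_hits_fdr = sum(x$associations$q < x$log$thresholds$fdr_threshold),
    n_flagged = sum(x$associations$flags != ""),
    decision = if (is.null(x$overlap)) NA_character_ else x$overlap$decision
  )
}
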