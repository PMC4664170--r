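#' Cis features testable against a SNP
#'
#' Collects the features whose gene lies within `window` bases of the SNP:
#' exons of genes with two or more exons, all exon--exon junctions, and
#' transcripts of genes with two or more annotated transcripts.
#'
#' @param snp list/tibble row with `chr` and `pos`, or a numeric position
#'   (then `chr` is taken from the gene model's first gene).
#' @param gene_model a [gene_model()].
#' @param window cis window half-width in bases (500 kb by default).
#' @return tibble with columns `feature_id`, `feature_kind`, `gene_id`.
#' @export
cis_features <- function(snp, gene_model, window = 500000) {
  if (is.numeric(snp)) snp <- list(chr = gene_model$genes$chr[1], pos = snp)
  genes <- gene_model$genes %>%
    filter(.data$chr == snp$chr,
           .data$start <= snp$pos + window,
           .data$end >= snp$pos - window) %>%
    pull("gene_id")
  if (length(genes) == 0) {
    return(tibble(feature_id = character(), feature_kind = character(),
                  gene_id = character()))
  }
  ex_counts <- gene_model$exons %>% count(.data$gene_id, name = "n_exons")
  tx_counts <- gene_model$transcripts %>%
    distinct(.data$gene_id, .data$transcript_id) %>%
    count(.data$gene_id, name = "n_tx")
  multi_exon <- ex_counts$gene_id[ex_counts$n_exons >= 2]
  multi_tx <- tx_counts$gene_id[tx_counts$n_tx >= 2]
  bind_rows(
    gene_model$exons %>%
      filter(.data$gene_id %in% genes, .data$gene_id %in% multi_exon) %>%
      transmute_feature("exon_id", "exon"),
    gene_model$junctions %>%
      filter(.data$gene_id %in% genes) %>%
      transmute_feature("junction_id", "junction"),
    gene_model$transcripts %>%
      distinct(.data$gene_id, .data$transcript_id) %>%
      filter(.data$gene_id %in% genes, .data$gene_id %in% multi_tx) %>%
      transmute_feature("transcript_id", "transcript")
  )
}

transmute_feature <- function(df, id_col, kind) {
  tibble(feature_id = df[[id_col]], feature_kind = kind,
         gene_id = df$gene_id)
}

# shared OLS core for the three association models; the response and the
# gene-expression covariate arrive already rank-normalized
fit_assoc <- function(y, g, gene_covariate, covariates,
                      snp_id = "snp", feature_id = "feature",
                      feature_kind = "exon", gene_id = NA_character_) {
  if (var(g) == 0) stop("monomorphic SNP", call. = FALSE)
  cv <- covariate_matrix(covariates)
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(gene_covariate)) X <- cbind(X, gene_expr = gene_covariate)
  if (!is.null(cv) && ncol(cv) > 0) X <- cbind(X, cv)
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (n <= ncol(X)) stop("fewer samples than model parameters", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrX, y)
  res <- y - drop(X %*% coef)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tstat <- coef / se
  p <- 2 * pt(-abs(tstat), df)
  tibble(
    snp_id = snp_id, feature_id = feature_id, feature_kind = feature_kind,
    gene_id = gene_id, beta1 = unname(coef["g"]), se = unname(se["g"]),
    statistic = unname(tstat["g"]), p = unname(p["g"]),
    df = df, n_samples = n, flags = ""
  )
}

#' Exon-level splicing association
#'
#' Regresses the rank-normalized RPKM of one exon on SNP dosage, adjusting
#' for overall gene expression via the leave-one-exon-out sum (the raw
#' RPKM of the gene's *other* exons, rank-normalized) so genes with few
#' exons do not lose power to a covariate nearly collinear with the
#' response, plus genotype PCs and hidden expression factors. Two-sided p
#' from the t distribution with `n - (parameters)` degrees of freedom.
#'
#' @param g dosage vector in `[0, 2]`.
#' @param exon_matrix samples x exons raw RPKM matrix for the gene.
#' @param exon_index column of the tested exon.
#' @param covariates a `covariate_set`, a numeric matrix, or NULL.
#' @param snp_id,gene_id identifiers carried into the record.
#' @return one-row association tibble: snp_id, feature_id, feature_kind,
#'   gene_id, beta1, se, statistic, p, df, n_samples, flags.
#' @export
exon_association <- function(g, exon_matrix, exon_index, covariates = NULL,
                             snp_id = "snp", gene_id = NA_character_) {
  exon_matrix <- as.matrix(exon_matrix)
  if (ncol(exon_matrix) < 2) {
    stop("exon test requires a gene with >= 2 exons", call. = FALSE)
  }
  y <- rank_normalize(exon_matrix[, exon_index])
  loo <- rank_normalize(rowSums(exon_matrix[, -exon_index, drop = FALSE]))
  fid <- colnames(exon_matrix)[exon_index] %||% paste0("exon_", exon_index)
  fit_assoc(y, g, loo, covariates, snp_id = snp_id, feature_id = fid,
            feature_kind = "exon", gene_id = gene_id)
}

#' Junction-level splicing association
#'
#' Rank-normalized junction RPM regressed on dosage, adjusting for
#' rank-normalized overall gene abundance plus PCs and hidden factors.
#'
#' @param g dosage vector.
#' @param junction_vector per-sample junction RPM.
#' @param gene_abundance per-sample gene abundance (RSEM-style).
#' @inheritParams exon_association
#' @param feature_id junction identifier for the record.
#' @return one-row association tibble.
#' @export
junction_association <- function(g, junction_vector, gene_abundance,
                                 covariates = NULL, snp_id = "snp",
                                 feature_id = "junction",
                                 gene_id = NA_character_) {
  fit_assoc(rank_normalize(junction_vector), g,
            rank_normalize(gene_abundance), covariates,
            snp_id = snp_id, feature_id = feature_id,
            feature_kind = "junction", gene_id = gene_id)
}

#' Transcript-level splicing association
#'
#' Rank-normalized transcript abundance regressed on dosage with the same
#' adjustment as the junction test. Callers should pre-filter transcripts
#' with [filter_transcripts()].
#'
#' @inheritParams junction_association
#' @param transcript_vector per-sample transcript abundance.
#' @return one-row association tibble.
#' @export
transcript_association <- function(g, transcript_vector, gene_abundance,
                                   covariates = NULL, snp_id = "snp",
                                   feature_id = "transcript",
                                   gene_id = NA_character_) {
  fit_assoc(rank_normalize(transcript_vector), g,
            rank_normalize(gene_abundance), covariates,
            snp_id = snp_id, feature_id = feature_id,
            feature_kind = "transcript", gene_id = gene_id)
}

#' Benjamini--Hochberg q-values
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @return step-up q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Scan all cis features of a locus against a set of SNPs
#'
#' Runs the exon, junction and transcript tests for every (SNP, feature)
#' pair returned by [cis_features()], applies the transcript
#' zero-expression filter, and attaches BH q-values. FDR is controlled
#' within each feature family by default (exon, junction and transcript
#' tests form separate families), or pooled across all tests.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression an `expression_set` on the same samples.
#' @param covariates a `covariate_set` (or NULL for unadjusted tests).
#' @param snp_ids SNPs to test; default all in the panel.
#' @param window cis window half-width.
#' @param fdr_family `"per_kind"` or `"pooled"`.
#' @param max_zero_fraction transcript filter threshold.
#' @return association tibble, class `sqtl_assoc`, one row per test with
#'   `q` added.
#' @export
sqtl_scan <- function(genotypes, expression, covariates = NULL,
                      snp_ids = NULL, window = 500000,
                      fdr_family = c("per_kind", "pooled"),
                      max_zero_fraction = 0.25) {
  fdr_family <- match.arg(fdr_family)
  gm <- expression$gene_model
  snp_ids <- snp_ids %||% genotypes$snp_info$snp_id
  kept_tx <- filter_transcripts(expression$transcript, max_zero_fraction)

  recs <- purrr::map_dfr(snp_ids, function(sid) {
    info <- genotypes$snp_info[genotypes$snp_info$snp_id == sid, ]
    g <- genotypes$dosages[, sid]
    feats <- cis_features(list(chr = info$chr, pos = info$pos), gm, window)
    purrr::map_dfr(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      gene_ab <- expression$gene[, f$gene_id]
      switch(
        f$feature_kind,
        exon = {
          ex_ids <- gm$exons$exon_id[gm$exons$gene_id == f$gene_id]
          exon_association(g, expression$exon[, ex_ids, drop = FALSE],
                           which(ex_ids == f$feature_id), covariates,
                           snp_id = sid, gene_id = f$gene_id)
        },
        junction = junction_association(
          g, expression$junction[, f$feature_id], gene_ab, covariates,
          snp_id = sid, feature_id = f$feature_id, gene_id = f$gene_id),
        transcript = {
          if (!f$feature_id %in% kept_tx) return(tibble())
          transcript_association(
            g, expression$transcript[, f$feature_id], gene_ab, covariates,
            snp_id = sid, feature_id = f$feature_id, gene_id = f$gene_id)
        }
      )
    })
  })
  if (nrow(recs) == 0) return(structure(recs, class = c("sqtl_assoc", class(recs))))
  recs <- if (fdr_family == "per_kind") {
    recs %>% group_by(.data$feature_kind) %>%
      mutate(q = bh_fdr(.data$p)) %>% ungroup()
  } else {
    recs %>% mutate(q = bh_fdr(.data$p))
  }
  structure(recs, class = c("sqtl_assoc", class(recs)))
}

add_flag <- function(flags, flag, on) {
  ifelse(on & !grepl(flag, flags, fixed = TRUE),
         ifelse(flags == "", flag, paste(flags, flag, sep = ";")), flags)
}

#' Corroborate transcript-level hits with exon/junction evidence
#'
#' Transcript reconstruction is error-prone, so a significant transcript
#' association (q below `fdr_threshold`) must be supported by a nominally
#' significant exon- or junction-level association at the same gene--SNP
#' pair whose direction is consistent with the transcript's composition:
#' a supporting feature contained in the transcript must share the sign of
#' the transcript's effect, one excluded from it must have the opposite
#' sign. Unsupported transcript hits gain the `transcript_uncorroborated`
#' flag (nothing is dropped; exclusion is a reporting decision).
#'
#' @param records an association tibble from [sqtl_scan()] with `q`.
#' @param gene_model the [gene_model()] the records refer to.
#' @param fdr_threshold transcript significance threshold on q.
#' @param support_p nominal significance threshold for supporting features.
#' @return the records with updated `flags`.
#' @export
corroborate_transcript_hits <- function(records, gene_model,
                                        fdr_threshold = 0.05,
                                        support_p = 0.05) {
  tx_rows <- which(records$feature_kind == "transcript" &
                     records$q < fdr_threshold)
  if (length(tx_rows) == 0) return(records)
  fmap <- transcript_feature_map(gene_model)
  for (i in tx_rows) {
    tx <- records$feature_id[i]
    contained <- fmap$feature_id[fmap$transcript_id == tx]
    cand <- records %>%
      filter(.data$snp_id == records$snp_id[i],
             .data$gene_id == records$gene_id[i],
             .data$feature_kind %in% c("exon", "junction"),
             .data$p < support_p)
    consistent <- ifelse(
      cand$feature_id %in% contained,
      sign(cand$beta1) == sign(records$beta1[i]),
      sign(cand$beta1) == -sign(records$beta1[i])
    )
    if (!any(consistent)) {
      records$flags[i] <- add_flag(records$flags[i],
                                   "transcript_uncorroborated", TRUE)
    }
  }
  records
}

#' Flag genes with paralogs or pseudogenes elsewhere in the genome
#'
#' Reads from a gene with a near-identical homolog can be misplaced by the
#' aligner, and genetic variation exacerbates the bias, so associations at
#' such genes are flagged `paralog_suspect` for reporting review.
#'
#' @param records association tibble.
#' @param paralog_table tibble with column `gene_id` (one row per gene
#'   having a homolog locus; further columns are ignored).
#' @return the records with updated `flags`.
#' @export
flag_paralogs <- function(records, paralog_table) {
  if (is.null(paralog_table) || nrow(paralog_table) == 0) return(records)
  unknown <- setdiff(paralog_table$gene_id, records$gene_id)
  if (length(unknown) > 0) {
    warning("paralog table lists gene(s) absent from the records: ",
            paste(unknown, collapse = ", "))
  }
  records$flags <- add_flag(records$flags, "paralog_suspect",
                            records$gene_id %in% paralog_table$gene_id)
  records
}
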