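# TSV readers/writers for the pipeline's interchange formats. All genomic
# coordinates are 0-based half-open internally (BED convention); VCF input
# positions (1-based) are shifted on read.

write_matrix_tsv <- function(m, path) {
  df <- as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a genotype matrix as TSV
#'
#' Two files: `<stem>_dosages.tsv` (samples x SNPs, `sample_id` first
#' column) and `<stem>_snps.tsv` (snp_id, chr, pos, ref, alt, maf, info).
#'
#' @param genotypes a `genotype_matrix`.
#' @param stem path stem without suffix.
#' @return (write) the stem, invisibly; (read) a `genotype_matrix`.
#' @export
write_genotypes_tsv <- function(genotypes, stem) {
  write_matrix_tsv(genotypes$dosages, paste0(stem, "_dosages.tsv"))
  readr::write_tsv(genotypes$snp_info, paste0(stem, "_snps.tsv"))
  invisible(stem)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(stem) {
  structure(
    list(dosages = read_matrix_tsv(paste0(stem, "_dosages.tsv")),
         snp_info = readr::read_tsv(
           paste0(stem, "_snps.tsv"), show_col_types = FALSE,
           col_types = readr::cols(
             snp_id = readr::col_character(),
             chr = readr::col_character(),
             ref = readr::col_character(),
             alt = readr::col_character(),
             maf = readr::col_double(),
             info = readr::col_double()))),
    class = "genotype_matrix"
  )
}

#' Write / read the expression component tables
#'
#' One TSV per component (`exon`, `junction`, `transcript`, `gene`,
#' `junction_counts`) plus per-sample totals, under `dir`.
#'
#' @param expression an `expression_set`.
#' @param dir output directory (created if needed).
#' @param gene_model (read) the [gene_model()] the tables belong to.
#' @param truth (read) optional [splice_effect_truth()] to reattach.
#' @return (write) `dir`, invisibly; (read) an `expression_set`.
#' @export
write_expression_tsv <- function(expression, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (comp in c("exon", "junction", "transcript", "gene", "junction_counts")) {
    write_matrix_tsv(expression[[comp]], file.path(dir, paste0(comp, ".tsv")))
  }
  readr::write_tsv(
    tibble(sample_id = rownames(expression$exon),
           total_mapped_reads = expression$total_mapped_reads),
    file.path(dir, "totals.tsv")
  )
  invisible(dir)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(dir, gene_model, truth = NULL) {
  comps <- lapply(
    setNames(nm = c("exon", "junction", "transcript", "gene",
                    "junction_counts")),
    function(comp) read_matrix_tsv(file.path(dir, paste0(comp, ".tsv")))
  )
  totals <- readr::read_tsv(file.path(dir, "totals.tsv"),
                            show_col_types = FALSE)
  structure(
    c(comps,
      list(total_mapped_reads = totals$total_mapped_reads,
           gene_model = gene_model, truth = truth, psi = NULL,
           confounders = NULL)),
    class = "expression_set"
  )
}

#' Write / read a gene model as a single TSV
#'
#' Long format with a `record` discriminator: `gene` and `exon` rows carry
#' BED-style 0-based half-open coordinates; `transcript_exon` rows list
#' each transcript's exons. Junctions are re-derived on read.
#'
#' @param gm a [gene_model()].
#' @param path TSV path.
#' @return (write) `path`, invisibly; (read) a [gene_model()].
#' @export
write_gene_model_tsv <- function(gm, path) {
  rows <- bind_rows(
    gm$genes %>% mutate(record = "gene", exon_id = NA_character_,
                        transcript_id = NA_character_),
    gm$exons %>% mutate(record = "exon", transcript_id = NA_character_),
    gm$transcripts %>% mutate(record = "transcript_exon",
                              chr = NA_character_, start = NA_real_,
                              end = NA_real_)
  ) %>%
    select("record", "gene_id", "chr", "start", "end", "exon_id",
           "transcript_id")
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_gene_model_tsv
#' @export
read_gene_model_tsv <- function(path) {
  rows <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            chr = readr::col_character(),
                            exon_id = readr::col_character(),
                            transcript_id = readr::col_character()))
  gene_model(
    genes = rows %>% filter(.data$record == "gene") %>%
      select("gene_id", "chr", "start", "end"),
    exons = rows %>% filter(.data$record == "exon") %>%
      select("exon_id", "gene_id", "chr", "start", "end"),
    transcripts = rows %>% filter(.data$record == "transcript_exon") %>%
      select("transcript_id", "gene_id", "exon_id")
  )
}

#' Write / read GWAS-style summary statistics
#'
#' TSV columns: snp_id, chr, pos, effect_allele, other_allele, z (plus any
#' further metadata). The LD matrix travels separately (see
#' [write_ld_tsv()]).
#'
#' @param stats a `summary_stats` object.
#' @param path TSV path.
#' @param ld (read) LD matrix or LD tibble for the same SNPs.
#' @return (write) `path`, invisibly; (read) a `summary_stats`.
#' @export
write_summary_stats_tsv <- function(stats, path) {
  readr::write_tsv(tidy(stats), path)
  invisible(path)
}

#' @rdname write_summary_stats_tsv
#' @export
read_summary_stats_tsv <- function(path, ld) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"z" %in% names(df)) {
    if (!all(c("p", "beta") %in% names(df))) {
      stop("summary statistics need either z or (p, beta) columns",
           call. = FALSE)
    }
    df$z <- z_from_p_and_beta(df$p, df$beta)
  }
  if (inherits(ld, "data.frame")) {
    ld <- ld_table_to_matrix(ld, df$snp_id)
  }
  summary_stats(df$z, ld, df %>% select(-"z"))
}

#' Write / read an LD table (snp_a, snp_b, r2)
#'
#' @param ld tibble from [ld_from_dosages()] or a correlation matrix
#'   (converted to squared entries).
#' @param path TSV path.
#' @return (write) `path`, invisibly; (read) the LD tibble.
#' @export
write_ld_tsv <- function(ld, path) {
  if (is.matrix(ld)) {
    ld <- as_tibble(ld^2, rownames = "snp_a") %>%
      tidyr::pivot_longer(-"snp_a", names_to = "snp_b", values_to = "r2")
  }
  readr::write_tsv(ld, path)
  invisible(path)
}

#' @rdname write_ld_tsv
#' @export
read_ld_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

ld_table_to_matrix <- function(ld_tbl, snp_ids) {
  m <- matrix(0, length(snp_ids), length(snp_ids),
              dimnames = list(snp_ids, snp_ids))
  keep <- ld_tbl$snp_a %in% snp_ids & ld_tbl$snp_b %in% snp_ids
  ld_tbl <- ld_tbl[keep, ]
  m[cbind(ld_tbl$snp_a, ld_tbl$snp_b)] <- sqrt(ld_tbl$r2)
  m[cbind(ld_tbl$snp_b, ld_tbl$snp_a)] <- sqrt(ld_tbl$r2)
  diag(m) <- 1
  m
}

#' Write / read the ground-truth record of a simulation
#'
#' @param truth a [splice_effect_truth()].
#' @param path JSON path.
#' @return (write) `path`, invisibly; (read) a [splice_effect_truth()].
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  splice_effect_truth(x$causal_snp_index, x$baseline_logit_psi,
                      x$effect_per_allele, x$affected_transcript_id,
                      x$gene_id)
}

#' Read dosages from a VCF with a DS (dosage) FORMAT field
#'
#' Thin adapter over \pkg{vcfR}; positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  dos <- t(ds)
  colnames(dos) <- fix[, "ID"]
  structure(
    list(
      dosages = dos,
      snp_info = tibble(
        snp_id = fix[, "ID"], chr = fix[, "CHROM"],
        pos = as.numeric(fix[, "POS"]) - 1,  # VCF is 1-based
        ref = fix[, "REF"], alt = fix[, "ALT"],
        maf = colMeans(dos) / 2, info = NA_real_
      )
    ),
    class = "genotype_matrix"
  )
}
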