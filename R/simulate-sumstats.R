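#' Simulate GWAS summary statistics at a locus
#'
#' Draws a z-score vector from the single-causal-variant model: with SNP c
#' causal and non-centrality lambda, `Z ~ MVN(lambda * Sigma[, c], Sigma)`
#' where Sigma is the LD correlation matrix. Marginal variances are 1 and
#' the expected z of SNP j is lambda times its LD r with the causal SNP.
#'
#' @param ld LD correlation matrix (symmetric PSD, unit diagonal) or an
#'   [ld_block_spec()] from which it is built.
#' @param causal_index index of the causal SNP.
#' @param lambda_ncp non-centrality (expected z at the causal SNP).
#' @param seed integer seed.
#' @param snp_info optional tibble of SNP metadata (snp_id, pos, ...) to
#'   attach; defaults to ids snp_001...
#' @return object of class `summary_stats`: list with `snp_ids`, `z`,
#'   `sigma`, `meta` (tibble with at least snp_id, pos, maf, info).
#' @export
simulate_summary_stats <- function(ld, causal_index, lambda_ncp = 0,
                                   seed = NULL, snp_info = NULL) {
  if (inherits(ld, "ld_block_spec")) {
    if (is.null(snp_info)) {
      snp_info <- tibble(
        snp_id = sprintf("snp_%03d", seq_len(ld$n_snps)),
        chr = ld$chr, pos = ld$positions, maf = ld$mafs, info = NA_real_
      )
    }
    ld <- block_ld_matrix(ld)
  }
  ld <- as.matrix(ld)
  n <- nrow(ld)
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)) ||
      any(abs(diag(ld) - 1) > 1e-8)) {
    stop("LD matrix must be symmetric with unit diagonal", call. = FALSE)
  }
  if (causal_index < 1 || causal_index > n) {
    stop("causal_index out of range", call. = FALSE)
  }
  # PSD guard: chol on a minimally ridged copy for the sampling root
  L <- tryCatch(chol(ld + 1e-10 * diag(n)), error = function(e)
    stop("LD matrix is not positive semi-definite", call. = FALSE))

  with_local_seed(seed, {
    z <- as.numeric(lambda_ncp * ld[, causal_index] +
                      drop(crossprod(L, rnorm(n))))
    summary_stats(
      z = z, sigma = ld,
      meta = snp_info %||% tibble(
        snp_id = sprintf("snp_%03d", seq_len(n)), chr = "chr1",
        pos = 10000 + (seq_len(n) - 1) * 5000, maf = NA_real_, info = NA_real_
      )
    )
  })
}

#' Bundle z-scores with their LD matrix
#'
#' @param z numeric vector of association z-scores (finite).
#' @param sigma LD correlation matrix (unit diagonal, |r| <= 1).
#' @param meta tibble of per-SNP metadata; must contain `snp_id`, and may
#'   carry `pos`, `maf`, `info`, `effect_allele`, `other_allele`.
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(z, sigma, meta) {
  sigma <- as.matrix(sigma)
  meta <- as_tibble(meta)
  stopifnot(length(z) == nrow(sigma), nrow(meta) == length(z),
            "snp_id" %in% names(meta))
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  if (any(abs(sigma) > 1 + 1e-8)) {
    stop("LD entries must satisfy |r| <= 1", call. = FALSE)
  }
  dimnames(sigma) <- list(meta$snp_id, meta$snp_id)
  structure(list(snp_ids = meta$snp_id, z = setNames(z, meta$snp_id),
                 sigma = sigma, meta = meta),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> ", length(x$z), " SNPs; |z| max ",
      signif(max(abs(x$z)), 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn summary_stats per-SNP tibble of z-scores and metadata.
#' @param x a `summary_stats`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.summary_stats <- function(x, ...) {
  x$meta %>% mutate(z = unname(x$z[.data$snp_id]))
}
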