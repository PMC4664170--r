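# run code under a private RNG stream, leaving the caller's untouched
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a locus of SNPs in LD blocks
#'
#' Describes the linkage-disequilibrium structure of a simulated locus:
#' SNPs fall into blocks, correlation is `within_block_r` for every pair
#' inside a block and zero across blocks (block-constant exchangeable
#' correlation, which is positive definite for r < 1).
#'
#' @param block_sizes integer vector; number of SNPs per block.
#' @param within_block_r latent haplotype correlation within a block,
#'   in `[0, 1)`. Scalar or one value per block.
#' @param mafs minor-allele frequencies in `(0, 0.5]`; scalar recycled or
#'   one value per SNP.
#' @param positions optional base-pair positions (defaults to a 5 kb grid).
#' @param chr chromosome label.
#' @return object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(block_sizes, within_block_r = 0, mafs = 0.3,
                          positions = NULL, chr = "chr1") {
  block_sizes <- as.integer(block_sizes)
  n_snps <- sum(block_sizes)
  stopifnot(n_snps >= 1, all(block_sizes >= 1))
  r <- rep_len(within_block_r, length(block_sizes))
  if (any(r < 0 | r >= 1)) {
    bad <- which(r < 0 | r >= 1)[1]
    stop("block ", bad, ": within_block_r must be in [0, 1) for a positive ",
         "definite correlation matrix", call. = FALSE)
  }
  mafs <- rep_len(mafs, n_snps)
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("mafs must lie in (0, 0.5]", call. = FALSE)
  }
  if (is.null(positions)) positions <- 10000 + (seq_len(n_snps) - 1L) * 5000
  stopifnot(length(positions) == n_snps)
  structure(
    list(n_snps = n_snps, block_sizes = block_sizes, within_block_r = r,
         mafs = mafs, positions = as.numeric(positions), chr = chr),
    class = "ld_block_spec"
  )
}

# block-constant correlation matrix implied by an ld_block_spec
block_ld_matrix <- function(spec) {
  blocks <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  r <- spec$within_block_r[blocks]
  R <- outer(blocks, blocks, "==") * sqrt(outer(r, r))
  diag(R) <- 1
  R
}

#' Simulate dosage genotypes under block LD
#'
#' Each sample receives two haplotypes drawn from a latent Gaussian copula
#' with the block-exchangeable correlation of `spec`; each latent value is
#' thresholded at the normal quantile of the SNP's allele frequency, and
#' the dosage is the sum of the two haplotype alleles. Dosages are
#' therefore integers in `{0, 1, 2}` unless `imputation_noise_sd > 0`,
#' which jitters them inside `[0, 2]` to emulate imputed dosages (the
#' means of the posterior genotype distribution).
#'
#' @param spec an [ld_block_spec()].
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed; identical `(spec, n_samples, seed)` give
#'   bit-identical output.
#' @param imputation_noise_sd optional truncation-free jitter SD; 0 keeps
#'   hard genotype calls.
#' @return object of class `genotype_matrix`: list with `dosages`
#'   (samples x SNPs numeric matrix, dimnames set) and `snp_info`
#'   (tibble: snp_id, chr, pos, ref, alt, maf, info, block).
#' @examples
#' g <- simulate_genotypes(ld_block_spec(c(3, 2), 0.8), 100, seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(spec, n_samples, seed = NULL,
                               imputation_noise_sd = 0) {
  stopifnot(inherits(spec, "ld_block_spec"), n_samples >= 2)
  with_local_seed(seed, {
    blocks <- rep(seq_along(spec$block_sizes), spec$block_sizes)
    thr <- qnorm(spec$mafs)
    hap <- function() {
      # exchangeable within-block correlation r = shared^2 loading
      z <- matrix(rnorm(n_samples * spec$n_snps), n_samples, spec$n_snps)
      for (b in seq_along(spec$block_sizes)) {
        idx <- which(blocks == b)
        r <- spec$within_block_r[b]
        if (r > 0 && length(idx) > 1) {
          shared <- rnorm(n_samples)
          z[, idx] <- sqrt(r) * shared + sqrt(1 - r) * z[, idx]
        }
      }
      # allele = 1 (alt) when the latent value falls below the MAF quantile
      sweep(z, 2, thr, "<") * 1
    }
    dos <- hap() + hap()
    if (imputation_noise_sd > 0) {
      dos <- dos + rnorm(length(dos), 0, imputation_noise_sd)
      dos <- pmin(pmax(dos, 0), 2)
    }
    snp_ids <- sprintf("snp_%03d", seq_len(spec$n_snps))
    dimnames(dos) <- list(sprintf("S%04d", seq_len(n_samples)), snp_ids)
    structure(
      list(
        dosages = dos,
        snp_info = tibble(
          snp_id = snp_ids, chr = spec$chr, pos = spec$positions,
          ref = "A", alt = "G", maf = spec$mafs, info = NA_real_,
          block = blocks
        )
      ),
      class = "genotype_matrix"
    )
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " SNPs\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_genotypes dosages as a long tibble
#'   (sample_id, snp_id, dosage).
#' @param x a `genotype_matrix`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.genotype_matrix <- function(x, ...) {
  as_tibble(x$dosages, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "snp_id",
                        values_to = "dosage")
}

#' Pairwise LD (r-squared) from a dosage matrix
#'
#' Squared Pearson correlation of dosages, the in-sample stand-in for an
#' external reference-panel LD table.
#'
#' @param genotypes a `genotype_matrix` or a samples x SNPs matrix.
#' @return tibble with columns `snp_a`, `snp_b`, `r2` (both orders plus
#'   self-pairs, so lookups need no symmetrization).
#' @export
ld_from_dosages <- function(genotypes) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  keep <- apply(dos, 2, function(v) var(v) > 0)
  dos <- dos[, keep, drop = FALSE]
  r2 <- cor(dos)^2
  as_tibble(r2, rownames = "snp_a") %>%
    tidyr::pivot_longer(-"snp_a", names_to = "snp_b", values_to = "r2")
}
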