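#' Rank-based inverse normal transformation
#'
#' Replaces each value by its fractional rank mapped onto the standard
#' normal: `qnorm((rank - 0.5) / n)`, with average ranks for ties. The
#' half-offset keeps the extremes finite and the output symmetric; the
#' transform is invariant under any strictly monotone transform of the
#' input.
#'
#' @param values numeric vector, finite, length >= 1.
#' @return numeric vector of normal scores, same length and order.
#' @examples
#' rank_normalize(c(1, 2, 3))   # -0.967, 0, 0.967
#' @export
rank_normalize <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.5) / length(values))
}

#' Reads-per-million from raw junction counts
#'
#' @param junction_counts raw read counts, one per sample.
#' @param total_mapped_reads total mapped reads per sample (> 0).
#' @return counts scaled per million mapped reads.
#' @export
counts_to_rpm <- function(junction_counts, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) {
    stop("total mapped reads must be positive", call. = FALSE)
  }
  junction_counts / (total_mapped_reads / 1e6)
}

#' Genotype principal components for ancestry adjustment
#'
#' EIGENSTRAT-convention PCA of the dosage matrix: each SNP is centred by
#' its mean dosage and scaled by `sqrt(p(1-p))` with `p = mean/2` (the
#' binomial SD of one allele draw), then the top-k left singular vectors
#' are returned. Monomorphic SNPs carry no ancestry information and are
#' dropped with a warning.
#'
#' @param genotypes a `genotype_matrix` or samples x SNPs dosage matrix.
#' @param k number of components.
#' @return samples x k matrix of principal components (columns PC1..PCk),
#'   with the singular values in attribute `d` and per-component variance
#'   fractions in attribute `variance_explained` so the scree is
#'   inspectable.
#' @export
genotype_pca <- function(genotypes, k = 3) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  mono <- apply(dos, 2, function(v) var(v) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped before PCA")
    dos <- dos[, !mono, drop = FALSE]
  }
  p <- colMeans(dos) / 2
  x <- sweep(dos, 2, 2 * p) %*% diag(1 / sqrt(p * (1 - p)), ncol(dos))
  sv <- svd(x, nu = min(dim(x)), nv = 0)
  r <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > r) stop("k = ", k, " exceeds the rank (", r, ") of the genotype matrix",
                  call. = FALSE)
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  dimnames(pcs) <- list(rownames(dos), paste0("PC", seq_len(k)))
  attr(pcs, "d") <- sv$d
  attr(pcs, "variance_explained") <- sv$d^2 / sum(sv$d^2)
  pcs
}

#' Hidden expression factors
#'
#' Surrogate-variable factors capturing global expression variability:
#' truncated SVD of the feature-centred `log2(RPKM + 0.25)` exon matrix.
#' The leading factors absorb batch, ancestry and other broad technical
#' structure so they can serve as regression covariates.
#'
#' @param exon_rpkm samples x exons RPKM matrix.
#' @param m number of factors; `m = 0` returns a zero-column matrix.
#' @return samples x m matrix (columns K1..Km), with attribute
#'   `variance_explained`.
#' @export
hidden_expression_factors <- function(exon_rpkm, m = 3) {
  x <- log2(as.matrix(exon_rpkm) + 0.25)
  x <- sweep(x, 2, colMeans(x))
  if (all(abs(x) < 1e-12)) stop("expression matrix is constant", call. = FALSE)
  if (m == 0) {
    out <- matrix(0, nrow(x), 0, dimnames = list(rownames(exon_rpkm), NULL))
    attr(out, "variance_explained") <- numeric(0)
    return(out)
  }
  if (nrow(x) < m + 1) stop("need at least m + 1 samples", call. = FALSE)
  sv <- svd(x, nu = m, nv = 0)
  f <- sv$u[, seq_len(m), drop = FALSE]
  dimnames(f) <- list(rownames(exon_rpkm), paste0("K", seq_len(m)))
  attr(f, "variance_explained") <- sv$d^2 / sum(sv$d^2)
  f
}

#' Filter transcripts by zero-expression fraction
#'
#' A transcript is testable only when it is expressed in most samples:
#' transcripts with zero expression in more than `max_zero_fraction` of
#' samples are removed (strict inequality, so exactly 25% of zeros keeps
#' the transcript under the default).
#'
#' @param transcript_matrix samples x transcripts abundance matrix.
#' @param max_zero_fraction largest tolerated fraction of zero-expression
#'   samples.
#' @return character vector of retained transcript ids.
#' @export
filter_transcripts <- function(transcript_matrix, max_zero_fraction = 0.25) {
  m <- as.matrix(transcript_matrix)
  if (length(m) == 0) stop("empty transcript matrix", call. = FALSE)
  zf <- colMeans(m == 0)
  colnames(m)[zf <= max_zero_fraction]
}

#' Assemble the regression covariate set
#'
#' Binds genotype principal components and hidden expression factors into
#' the samples x (k + m) covariate block the association models adjust
#' for, with columns centred.
#'
#' @param genotypes a `genotype_matrix`.
#' @param exon_rpkm samples x exons RPKM matrix (same sample order).
#' @param k number of genotype PCs (default 3).
#' @param m number of hidden factors (default 3).
#' @return object of class `covariate_set`: list with matrices `pcs` and
#'   `factors`, and `scree` (tibble of component, kind, variance_explained).
#' @export
build_covariates <- function(genotypes, exon_rpkm, k = 3, m = 3) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  stopifnot(nrow(dos) == nrow(exon_rpkm))
  pcs <- if (k > 0) genotype_pca(genotypes, k) else
    matrix(0, nrow(dos), 0, dimnames = list(rownames(dos), NULL))
  fac <- hidden_expression_factors(exon_rpkm, m)
  pcs_c <- sweep(pcs, 2, colMeans(pcs))
  fac_c <- if (ncol(fac) > 0) sweep(fac, 2, colMeans(fac)) else fac
  scree <- bind_rows(
    tibble(kind = "pc", component = seq_along(attr(pcs, "variance_explained")),
           variance_explained = attr(pcs, "variance_explained") %||% numeric(0)),
    tibble(kind = "factor",
           component = seq_along(attr(fac, "variance_explained")),
           variance_explained = attr(fac, "variance_explained") %||% numeric(0))
  )
  structure(list(pcs = pcs_c, factors = fac_c, scree = scree),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("<covariate_set> ", ncol(x$pcs), " PCs + ", ncol(x$factors),
      " hidden factors over ", nrow(x$pcs), " samples\n", sep = "")
  invisible(x)
}

#' @describeIn build_covariates covariates as a tibble
#'   (sample_id, PC1.., K1..).
#' @param x a `covariate_set`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.covariate_set <- function(x, ...) {
  as_tibble(cbind(x$pcs, x$factors), rownames = "sample_id")
}

covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "covariate_set")) {
    cbind(covariates$pcs, covariates$factors)
  } else if (is.matrix(covariates) || is.data.frame(covariates)) {
    as.matrix(covariates)
  } else {
    stop("covariates must be a covariate_set or a matrix", call. = FALSE)
  }
}
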