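#' Signed z-score from a two-sided p-value and effect direction
#'
#' `z = sign(beta) * qnorm(1 - p/2)`: the inverse normal transform of a
#' two-sided p-value, signed by the regression coefficient. t-derived
#' p-values are treated as normal, a negligible approximation at the
#' sample sizes the tests run on.
#'
#' @param p two-sided p-value(s) in `(0, 1]`.
#' @param beta effect estimate(s) supplying the sign.
#' @return numeric z-score(s).
#' @examples
#' z_from_p_and_beta(0.05, -1)  # -1.96
#' @export
z_from_p_and_beta <- function(p, beta) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  z <- qnorm(p / 2, lower.tail = FALSE)
  ifelse(p == 1, 0, sign(beta) * z)
}

#' Log-likelihood of each SNP being the single causal variant
#'
#' Under a single-causal-variant model, if SNP i is causal the expected
#' z-scores across the locus are `M_i = z_i * Sigma[, i]` — the observed z
#' at i propagated through LD. The likelihood of SNP i is the multivariate
#' normal density of the observed vector Z with mean `M_i` and covariance
#' Sigma, computed in log space via the Cholesky factor. A small ridge on
#' the diagonal keeps perfect-LD pairs invertible.
#'
#' @param stats a `summary_stats` object (z, sigma).
#' @param ridge diagonal regularization added to Sigma.
#' @param keep_constant retain the MVN normalizing constant (it cancels in
#'   the posterior; keeping it makes the values true log-densities).
#' @return named numeric vector of per-SNP log-likelihoods.
#' @export
causal_log_likelihoods <- function(stats, ridge = 1e-6,
                                   keep_constant = TRUE) {
  stopifnot(inherits(stats, "summary_stats"))
  z <- stats$z
  S <- stats$sigma + ridge * diag(nrow(stats$sigma))
  L <- tryCatch(chol(S), error = function(e)
    stop("LD matrix is not positive definite even after ridge = ", ridge,
         "; increase the ridge", call. = FALSE))
  n <- length(z)
  const <- if (keep_constant) {
    -0.5 * n * log(2 * pi) - sum(log(diag(L)))
  } else 0
  ll <- vapply(seq_len(n), function(i) {
    resid <- z - z[i] * stats$sigma[, i]
    w <- backsolve(L, resid, transpose = TRUE)
    const - 0.5 * sum(w^2)
  }, numeric(1))
  setNames(ll, stats$snp_ids)
}

#' Posterior probability of causality per SNP
#'
#' Normalizes the per-SNP likelihoods to posteriors,
#' `P_i = l_i / sum_j l_j`, via log-sum-exp so extreme likelihood ratios
#' cannot underflow.
#'
#' @param log_likelihoods finite numeric vector of per-SNP log
#'   likelihoods (named by SNP id).
#' @param meta optional per-SNP metadata tibble (snp_id, pos, ...) carried
#'   along for credible-set tie-breaking and plotting.
#' @return object of class `causal_posteriors`: tibble with columns
#'   `snp_id`, `log_lik`, `posterior` (and any metadata columns),
#'   posteriors summing to 1.
#' @export
causal_posteriors <- function(log_likelihoods, meta = NULL) {
  if (length(log_likelihoods) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(log_likelihoods))) {
    stop("log-likelihoods must be finite", call. = FALSE)
  }
  m <- max(log_likelihoods)
  p <- exp(log_likelihoods - m)
  p <- p / sum(p)
  ids <- names(log_likelihoods) %||% sprintf("snp_%03d", seq_along(p))
  out <- tibble(snp_id = ids, log_lik = unname(log_likelihoods),
                posterior = unname(p))
  if (!is.null(meta)) {
    out <- out %>% left_join(as_tibble(meta), by = "snp_id")
  }
  structure(out, class = c("causal_posteriors", class(out)))
}

#' Fine-map a locus from summary statistics
#'
#' Convenience composition of [causal_log_likelihoods()] and
#' [causal_posteriors()].
#'
#' @inheritParams causal_log_likelihoods
#' @return a `causal_posteriors` tibble.
#' @export
finemap_locus <- function(stats, ridge = 1e-6, keep_constant = TRUE) {
  causal_posteriors(causal_log_likelihoods(stats, ridge, keep_constant),
                    meta = stats$meta)
}

#' Minimal credible set of causal candidates
#'
#' Orders SNPs by descending posterior (ties broken by genomic position,
#' then id, so the set is deterministic) and returns the smallest prefix
#' whose cumulative posterior reaches `threshold`.
#'
#' @param posteriors a `causal_posteriors` tibble (column `pos` used for
#'   tie-breaks when present).
#' @param threshold cumulative posterior the set must reach.
#' @return object of class `credible_set`: list with `snp_ids` (in
#'   inclusion order), `cumulative_probability`, `threshold`, `n_total`.
#' @export
credible_set <- function(posteriors, threshold = 0.95) {
  stopifnot(nrow(posteriors) >= 1, threshold <= 1)
  ord <- order(-posteriors$posterior,
               if ("pos" %in% names(posteriors)) posteriors$pos else
                 seq_len(nrow(posteriors)),
               posteriors$snp_id)
  p <- posteriors$posterior[ord]
  csum <- cumsum(p)
  k <- which(csum >= threshold)[1]
  if (is.na(k)) k <- length(p)
  k <- max(k, 1L)
  structure(
    list(snp_ids = posteriors$snp_id[ord][seq_len(k)],
         cumulative_probability = csum[k],
         threshold = threshold,
         n_total = nrow(posteriors)),
    class = "credible_set"
  )
}

#' @export
print.credible_set <- function(x, ...) {
  cat("<credible_set> ", length(x$snp_ids), " of ", x$n_total,
      " SNPs; cumulative posterior ", signif(x$cumulative_probability, 4),
      " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Cross-trait overlap of a credible set
#'
#' Sums the second trait's causal posteriors over the first trait's
#' credible set. When the set captures the causal variant of trait A with
#' probability >= 0.95 but carries < `exclusion_threshold` of trait B's
#' posterior mass, the two signals are unlikely to share a causal variant.
#'
#' @param set a [credible_set()] built from trait A.
#' @param posteriors_other a `causal_posteriors` tibble for trait B over
#'   the same SNP universe.
#' @param exclusion_threshold cumulative probability below which a shared
#'   causal variant is rejected.
#' @return object of class `overlap_result`: list with `set`,
#'   `other_trait_cumulative` and `decision` (one of
#'   `"different_causal_variant"`, `"shared_not_excluded"`).
#' @export
credible_set_overlap <- function(set, posteriors_other,
                                 exclusion_threshold = 0.05) {
  missing_ids <- setdiff(set$snp_ids, posteriors_other$snp_id)
  if (length(missing_ids) > 0) {
    stop("credible-set SNPs absent from the other trait: ",
         paste(head(missing_ids, 5), collapse = ", "),
         "; merge the SNP universes first", call. = FALSE)
  }
  cum <- sum(posteriors_other$posterior[
    posteriors_other$snp_id %in% set$snp_ids])
  structure(
    list(set = set,
         other_trait_cumulative = cum,
         decision = if (cum < exclusion_threshold)
           "different_causal_variant" else "shared_not_excluded"),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> other-trait cumulative probability ",
      signif(x$other_trait_cumulative, 3), " over a ",
      length(x$set$snp_ids), "-SNP set -> ", x$decision, "\n", sep = "")
  invisible(x)
}

#' Merge two traits onto a common SNP universe
#'
#' Intersects the SNP panels of two `summary_stats` objects, harmonizes
#' alleles (when one trait's effect allele is the other's other allele,
#' its z flips sign) and subsets both LD matrices consistently.
#'
#' @param stats_a,stats_b `summary_stats` objects whose `meta` may carry
#'   `effect_allele` / `other_allele` columns.
#' @return list with elements `a` and `b`, both `summary_stats` on the
#'   shared SNP list in a common order and allele frame (trait A's).
#' @export
merge_snp_universe <- function(stats_a, stats_b) {
  common <- intersect(stats_a$snp_ids, stats_b$snp_ids)
  if (length(common) == 0) {
    stop("the two traits share no SNPs", call. = FALSE)
  }
  sub <- function(s, ids) {
    idx <- match(ids, s$snp_ids)
    summary_stats(z = unname(s$z[idx]), sigma = s$sigma[idx, idx],
                  meta = s$meta[idx, ])
  }
  a <- sub(stats_a, common)
  b <- sub(stats_b, common)
  if (all(c("effect_allele", "other_allele") %in% names(a$meta)) &&
      all(c("effect_allele", "other_allele") %in% names(b$meta))) {
    swapped <- a$meta$effect_allele == b$meta$other_allele &
      a$meta$other_allele == b$meta$effect_allele
    mismatch <- !swapped & a$meta$effect_allele != b$meta$effect_allele
    if (any(mismatch)) {
      stop("allele mismatch beyond a swap at: ",
           paste(head(common[mismatch], 5), collapse = ", "), call. = FALSE)
    }
    if (any(swapped)) {
      zb <- b$z
      zb[swapped] <- -zb[swapped]
      meta_b <- b$meta
      meta_b$effect_allele <- a$meta$effect_allele
      meta_b$other_allele <- a$meta$other_allele
      b <- summary_stats(unname(zb), b$sigma, meta_b)
    }
  }
  list(a = a, b = b)
}

#' Fine-mapping SNP filter
#'
#' Keeps SNPs with minor allele frequency above `maf_min` and — for
#' imputed SNPs, i.e. those carrying an INFO score — imputation quality
#' above `info_min`. Genotyped SNPs (INFO missing) pass the INFO test.
#'
#' @param meta tibble with `snp_id`, `maf` and optionally `info`.
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param info_min minimum INFO score (exclusive) for imputed SNPs.
#' @return character vector of retained SNP ids.
#' @export
finemap_snp_filter <- function(meta, maf_min = 0.001, info_min = 0.5) {
  maf <- pmin(meta$maf, 1 - meta$maf)
  info_ok <- if ("info" %in% names(meta)) {
    is.na(meta$info) | meta$info > info_min
  } else TRUE
  meta$snp_id[maf > maf_min & info_ok]
}

#' @describeIn causal_posteriors one-row summary: number of SNPs, top SNP,
#'   top posterior, posterior entropy, size of the 95% credible set.
#' @param x a `causal_posteriors` tibble.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.causal_posteriors <- function(x, ...) {
  cs <- credible_set(x, 0.95)
  tibble(
    n_snps = nrow(x),
    top_snp = x$snp_id[which.max(x$posterior)],
    top_posterior = max(x$posterior),
    entropy = -sum(x$posterior * log(pmax(x$posterior, 1e-300))),
    n_credible_95 = length(cs$snp_ids)
  )
}

#' @describeIn credible_set_overlap overlap result as a one-row tibble
#'   mirroring a per-locus report (total SNPs, set size, set cumulative,
#'   other-trait cumulative, decision).
#' @param x an `overlap_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.overlap_result <- function(x, ...) {
  tibble(
    n_snps_total = x$set$n_total,
    n_snps_credible = length(x$set$snp_ids),
    set_cumulative = x$set$cumulative_probability,
    other_trait_cumulative = x$other_trait_cumulative,
    decision = x$decision
  )
}
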