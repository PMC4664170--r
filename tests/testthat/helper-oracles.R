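# Independent oracles used to cross-check the package's implementations.

# hand-rolled Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# dense multivariate normal log-density via determinant + solve (no
# Cholesky), used as the brute-force oracle for the causal likelihoods
mvn_logdens_oracle <- function(x, mu, sigma) {
  k <- length(x)
  r <- x - mu
  as.numeric(-0.5 * (k * log(2 * pi) + determinant(sigma)$modulus +
                       t(r) %*% solve(sigma) %*% r))
}

# random correlation matrix from a Wishart-style draw
random_corr <- function(n, df = n + 4) {
  a <- matrix(rnorm(n * df), df, n)
  stats::cov2cor(crossprod(a) / df + 0.05 * diag(n))
}

# small two-isoform locus used across association tests
make_locus <- function(n = 300, effect = 1.5, noise_sd = 0.2, seed = 1,
                       n_snps = 10, r = 0.8, maf = 0.3) {
  spec <- ld_block_spec(n_snps, r, mafs = maf)
  g <- simulate_genotypes(spec, n, seed = seed)
  gm <- example_gene_model()
  truth <- splice_effect_truth(1, 0, effect, "G1_T2", "G1")
  ex <- simulate_expression(g, gm, truth, noise_sd = noise_sd,
                            seed = seed + 1L)
  list(g = g, gm = gm, truth = truth, ex = ex)
}
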