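#' Ground-truth splicing effect for a simulated locus
#'
#' The causal SNP shifts the splicing proportion psi — the fraction of the
#' gene's output carried by the affected transcript — on the logit scale:
#' `psi(g) = logistic(baseline_logit_psi + effect_per_allele * g)` for
#' dosage g. `effect_per_allele = 0` is the null.
#'
#' @param causal_snp_index column index of the causal SNP in the locus.
#' @param baseline_logit_psi baseline log-odds of the affected isoform.
#' @param effect_per_allele per-allele shift in logit psi.
#' @param affected_transcript_id transcript whose share is psi.
#' @param gene_id gene the effect acts on.
#' @return object of class `splice_effect_truth`.
#' @export
splice_effect_truth <- function(causal_snp_index, baseline_logit_psi = 0,
                                effect_per_allele = 0,
                                affected_transcript_id, gene_id) {
  structure(
    list(causal_snp_index = as.integer(causal_snp_index),
         baseline_logit_psi = baseline_logit_psi,
         effect_per_allele = effect_per_allele,
         affected_transcript_id = affected_transcript_id,
         gene_id = gene_id),
    class = "splice_effect_truth"
  )
}

#' Simulate isoform-level expression driven by a splicing QTL
#'
#' Emulates the Level-3-style expression tables the association tests
#' consume. Per sample: total gene output is log-normal around
#' `base_gene_expression`; the affected transcript receives fraction
#' psi(g) of it and the remaining transcripts split 1 - psi equally; each
#' transcript abundance then gets multiplicative log-normal measurement
#' noise `exp(N(0, noise_sd))`. Exon values are sums of the abundances of
#' the transcripts containing the exon (RPKM-like density units), junction
#' values likewise over transcripts using the junction (RPM-like), and the
#' gene value is the transcript total. Hidden confounders load additively
#' on the log scale of every feature. Junction read counts are Poisson
#' around value x depth so the raw-count-to-RPM step can be exercised.
#'
#' @param genotypes a `genotype_matrix` containing the causal SNP.
#' @param gene_model a [gene_model()] with >= 2 transcripts and >= 2 exons.
#' @param truth a [splice_effect_truth()].
#' @param noise_sd SD of log-normal measurement noise on transcripts and
#'   feature read-offs.
#' @param n_confounders number of latent confounders (ancestry/batch) to
#'   plant; ignored when `confounders` is supplied.
#' @param confounder_strength scale of confounder loadings on
#'   log-expression.
#' @param confounders optional samples x q matrix of known confounder
#'   scores (e.g. a population indicator) to plant instead of drawing
#'   standard-normal ones.
#' @param base_gene_expression mean gene output in abundance units.
#' @param gene_sd SD of log-normal sample-to-sample gene output variation.
#' @param library_size mean total mapped reads per sample; actual totals
#'   vary log-normally (library-size variation).
#' @param seed integer seed.
#' @return object of class `expression_set`: matrices `exon`, `junction`,
#'   `transcript`, `gene` (samples x features), `junction_counts`,
#'   `total_mapped_reads`, plus `gene_model`, `truth`, `psi`,
#'   `confounders`.
#' @export
simulate_expression <- function(genotypes, gene_model, truth,
                                noise_sd = 0.3, n_confounders = 0,
                                confounder_strength = 0, confounders = NULL,
                                base_gene_expression = 100, gene_sd = 0.5,
                                library_size = 1e7, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(gene_model, "gene_model"),
            inherits(truth, "splice_effect_truth"))
  tx_ids <- unique(gene_model$transcripts$transcript_id)
  if (length(tx_ids) < 2 || nrow(gene_model$exons) < 2) {
    stop("gene model needs >= 2 transcripts and >= 2 exons", call. = FALSE)
  }
  if (!truth$affected_transcript_id %in% tx_ids) {
    stop("affected transcript not in gene model", call. = FALSE)
  }
  if (truth$causal_snp_index < 1 ||
      truth$causal_snp_index > ncol(genotypes$dosages)) {
    stop("causal SNP index outside the genotype matrix", call. = FALSE)
  }

  dos <- genotypes$dosages
  n <- nrow(dos)
  g <- dos[, truth$causal_snp_index]

  with_local_seed(seed, {
    psi <- stats::plogis(truth$baseline_logit_psi + truth$effect_per_allele * g)
    total <- base_gene_expression * exp(rnorm(n, 0, gene_sd))

    w <- matrix((1 - psi) / (length(tx_ids) - 1), n, length(tx_ids),
                dimnames = list(rownames(dos), tx_ids))
    w[, truth$affected_transcript_id] <- psi
    tx_noise <- matrix(exp(rnorm(n * length(tx_ids), 0, noise_sd)),
                       n, length(tx_ids))
    transcript <- w * total * tx_noise

    fmap <- transcript_feature_map(gene_model)
    read_off <- function(kind, ids) {
      m <- matrix(0, n, length(ids), dimnames = list(rownames(dos), ids))
      for (f in ids) {
        tx_in <- fmap$transcript_id[fmap$feature_id == f &
                                      fmap$feature_kind == kind]
        if (length(tx_in) > 0) {
          m[, f] <- rowSums(transcript[, tx_in, drop = FALSE])
        }
      }
      m * matrix(exp(rnorm(length(m), 0, noise_sd)), n, length(ids))
    }
    exon <- read_off("exon", gene_model$exons$exon_id)
    junction <- read_off("junction", gene_model$junctions$junction_id)
    gene <- matrix(rowSums(transcript), n, 1,
                   dimnames = list(rownames(dos), gene_model$genes$gene_id[1]))

    if (is.null(confounders) && n_confounders > 0) {
      confounders <- matrix(rnorm(n * n_confounders), n, n_confounders)
    }
    if (!is.null(confounders) && confounder_strength > 0) {
      confounders <- as.matrix(confounders)
      all_feats <- ncol(exon) + ncol(junction) + ncol(transcript) + 1L
      load <- matrix(rnorm(ncol(confounders) * all_feats, mean = 1, sd = 0.3),
                     ncol(confounders), all_feats)
      shift <- exp(confounder_strength * (confounders %*% load))
      k <- 0L
      bump <- function(m) {
        cols <- k + seq_len(ncol(m)); k <<- k + ncol(m)
        m * shift[, cols, drop = FALSE]
      }
      exon <- bump(exon); junction <- bump(junction)
      transcript <- bump(transcript); gene <- bump(gene)
    }

    total_reads <- round(library_size * exp(rnorm(n, 0, 0.2)))
    junction_counts <- matrix(
      rpois(length(junction), junction * outer(total_reads, rep(1, ncol(junction))) / 1e6),
      n, ncol(junction), dimnames = dimnames(junction)
    )

    structure(
      list(exon = exon, junction = junction, transcript = transcript,
           gene = gene, junction_counts = junction_counts,
           total_mapped_reads = total_reads, gene_model = gene_model,
           truth = truth, psi = psi, confounders = confounders),
      class = "expression_set"
    )
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$exon), " samples; ", ncol(x$exon),
      " exons, ", ncol(x$junction), " junctions, ", ncol(x$transcript),
      " transcripts\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_expression long tibble of all expression values
#'   (sample_id, feature_id, feature_kind, value).
#' @param x an `expression_set`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.expression_set <- function(x, ...) {
  one <- function(m, kind) {
    as_tibble(m, rownames = "sample_id") %>%
      tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                          values_to = "value") %>%
      mutate(feature_kind = kind)
  }
  bind_rows(one(x$exon, "exon"), one(x$junction, "junction"),
            one(x$transcript, "transcript"), one(x$gene, "gene")) %>%
    select("sample_id", "feature_id", "feature_kind", "value")
}
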