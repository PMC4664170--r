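#' Plot an association scan
#'
#' -log10 p-value per SNP--feature test, faceted by feature kind, with
#' the FDR-significant tests emphasized.
#'
#' @param object an `sqtl_assoc` tibble from [sqtl_scan()].
#' @param fdr_threshold q cut used for emphasis.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sqtl_assoc <- function(object, fdr_threshold = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(significant = .data$q < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_id,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_kind), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  colour = paste0("q < ", fdr_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot causal posteriors along the locus
#'
#' @param object a `causal_posteriors` tibble (uses `pos` when present).
#' @param credible_threshold members of this credible set are highlighted.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.causal_posteriors <- function(object, credible_threshold = 0.95,
                                       ...) {
  cs <- credible_set(object, credible_threshold)
  df <- as_tibble(object) %>%
    mutate(in_set = .data$snp_id %in% cs$snp_ids,
           x = if ("pos" %in% names(object)) .data$pos else
             seq_len(nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$posterior,
                                   colour = .data$in_set)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = if ("pos" %in% names(object)) "position (bp)" else
      "SNP index", y = "posterior P(causal)",
      colour = paste0(credible_threshold * 100, "% set")) +
    ggplot2::theme_minimal()
}

#' Scree plot of covariate components
#'
#' Variance explained by genotype PCs and hidden expression factors, the
#' view used to justify how many covariates the association models carry.
#'
#' @param object a `covariate_set`.
#' @param n_components how many leading components to show per kind.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.covariate_set <- function(object, n_components = 10, ...) {
  df <- object$scree %>%
    group_by(.data$kind) %>%
    filter(.data$component <= n_components) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$variance_explained)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind)) +
    ggplot2::labs(x = "component", y = "fraction of variance explained") +
    ggplot2::theme_minimal()
}
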