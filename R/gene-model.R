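#' Construct a gene model
#'
#' A gene model ties together the features the splicing tests operate on:
#' exons (0-based half-open coordinates, BED convention), exon--exon
#' junctions (donor = end of the upstream exon, acceptor = start of the
#' downstream exon) and transcripts as ordered exon sets. Junctions are
#' derived from the transcript structure: every pair of exons that are
#' consecutive within some transcript defines a junction.
#'
#' @param genes tibble with columns `gene_id`, `chr`, `start`, `end`.
#' @param exons tibble with columns `exon_id`, `gene_id`, `chr`, `start`,
#'   `end` (0-based half-open).
#' @param transcripts tibble with columns `transcript_id`, `gene_id`,
#'   `exon_id`: one row per exon of each transcript.
#' @return An object of class `gene_model`: a list with tibbles `genes`,
#'   `exons`, `transcripts` and the derived `junctions` (columns
#'   `junction_id`, `gene_id`, `chr`, `donor`, `acceptor`, `donor_exon`,
#'   `acceptor_exon`).
#' @examples
#' gm <- example_gene_model()
#' gm$junctions
#' @export
gene_model <- function(genes, exons, transcripts) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  transcripts <- as_tibble(transcripts)
  stopifnot(
    all(c("gene_id", "chr", "start", "end") %in% names(genes)),
    all(c("exon_id", "gene_id", "chr", "start", "end") %in% names(exons)),
    all(c("transcript_id", "gene_id", "exon_id") %in% names(transcripts))
  )
  if (any(exons$end <= exons$start)) {
    stop("gene model has exons with non-positive length", call. = FALSE)
  }
  bad_tx <- setdiff(transcripts$exon_id, exons$exon_id)
  if (length(bad_tx) > 0) {
    stop("transcripts reference unknown exons: ",
         paste(bad_tx, collapse = ", "), call. = FALSE)
  }
  n_ex <- transcripts %>% count(.data$transcript_id)
  if (any(n_ex$n < 1)) stop("transcript with no exons", call. = FALSE)

  junctions <- derive_junctions(exons, transcripts)
  structure(
    list(genes = genes, exons = exons, transcripts = transcripts,
         junctions = junctions),
    class = "gene_model"
  )
}

# junction = consecutive exon pair within a transcript, ordered by start
derive_junctions <- function(exons, transcripts) {
  tx_ex <- transcripts %>%
    left_join(exons, by = c("exon_id", "gene_id")) %>%
    arrange(.data$transcript_id, .data$start)
  pairs <- tx_ex %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chr) %>%
    dplyr::reframe(
      donor_exon = .data$exon_id[-n()],
      acceptor_exon = .data$exon_id[-1],
      donor = .data$end[-n()],
      acceptor = .data$start[-1],
      .groups = "drop"
    ) %>%
    distinct(.data$gene_id, .data$chr, .data$donor, .data$acceptor,
             .data$donor_exon, .data$acceptor_exon)
  pairs %>%
    arrange(.data$gene_id, .data$donor, .data$acceptor) %>%
    mutate(junction_id = paste0("J_", .data$donor_exon, "_", .data$acceptor_exon),
           .before = 1)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", nrow(x$genes), " gene(s), ", nrow(x$exons),
      " exons, ", nrow(x$junctions), " junctions, ",
      length(unique(x$transcripts$transcript_id)), " transcripts\n", sep = "")
  invisible(x)
}

#' Transcript-by-feature containment of a gene model
#'
#' @param gm a [gene_model()].
#' @return tibble with one row per (transcript, feature) containment:
#'   columns `transcript_id`, `gene_id`, `feature_id`, `feature_kind`.
#' @export
transcript_feature_map <- function(gm) {
  ex <- gm$transcripts %>%
    rename(feature_id = "exon_id") %>%
    mutate(feature_kind = "exon")
  # a transcript carries a junction iff it uses that consecutive exon pair
  tx_ids <- unique(gm$transcripts$transcript_id)
  jn <- purrr::map_dfr(tx_ids, function(tx) {
    ex_tx <- gm$transcripts$exon_id[gm$transcripts$transcript_id == tx]
    ord <- gm$exons %>% filter(.data$exon_id %in% ex_tx) %>% arrange(.data$start)
    if (nrow(ord) < 2) return(tibble())
    tibble(
      transcript_id = tx,
      gene_id = ord$gene_id[1],
      feature_id = paste0("J_", ord$exon_id[-nrow(ord)], "_", ord$exon_id[-1]),
      feature_kind = "junction"
    )
  })
  bind_rows(ex %>% select("transcript_id", "gene_id", "feature_id", "feature_kind"), jn)
}

#' Genomic interval(s) occupied by a feature
#'
#' Exons map to their own interval. A junction's "site" is the pair of
#' exonic flanks a junction-spanning read covers, so reads (and SNPs) on
#' either side of the splice can be attributed to it.
#'
#' @param gm a [gene_model()].
#' @param feature_id exon or junction identifier.
#' @param flank width in bases of the exonic segment on each side of a
#'   junction counted as part of its site (roughly a read length).
#' @return tibble with columns `chr`, `start`, `end` (0-based half-open),
#'   one row per interval.
#' @export
feature_intervals <- function(gm, feature_id, flank = 50) {
  if (feature_id %in% gm$exons$exon_id) {
    e <- gm$exons[gm$exons$exon_id == feature_id, ]
    return(tibble(chr = e$chr, start = e$start, end = e$end))
  }
  if (feature_id %in% gm$junctions$junction_id) {
    j <- gm$junctions[gm$junctions$junction_id == feature_id, ]
    return(tibble(
      chr = j$chr,
      start = c(max(j$donor - flank, 0L), j$acceptor),
      end = c(j$donor, j$acceptor + flank)
    ))
  }
  stop("unknown feature: ", feature_id, call. = FALSE)
}

#' A small two-isoform gene model used in examples and simulations
#'
#' One gene with three exons; transcript T1 uses all three, transcript T2
#' skips the cassette exon E2. The splicing proportion psi is the fraction
#' of the gene's output carried by T1, so exon E2 and junctions E1-E2 /
#' E2-E3 track psi while the skipping junction E1-E3 tracks 1 - psi.
#'
#' @param gene_id,chr identifiers for the gene.
#' @param offset genomic offset in bases added to all coordinates.
#' @return a [gene_model()].
#' @export
example_gene_model <- function(gene_id = "G1", chr = "chr1", offset = 0L) {
  ex_id <- function(k) paste0(gene_id, "_E", k)
  genes <- tibble(gene_id = gene_id, chr = chr,
                  start = offset + 1000L, end = offset + 3300L)
  exons <- tibble(
    exon_id = ex_id(1:3),
    gene_id = gene_id, chr = chr,
    start = offset + c(1000L, 2000L, 3000L),
    end   = offset + c(1200L, 2100L, 3300L)
  )
  transcripts <- tibble(
    transcript_id = rep(paste0(gene_id, c("_T1", "_T2")), c(3L, 2L)),
    gene_id = gene_id,
    exon_id = c(ex_id(1:3), ex_id(c(1, 3)))
  )
  gene_model(genes, exons, transcripts)
}
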