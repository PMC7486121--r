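#' 3' UTR length of every transcript
#'
#' Sums the closed-interval lengths (`end - start + 1`) of all
#' `three_prime_utr` segments per transcript. Transcripts with no such segment
#' get length 0. The stop codon is not part of the 3' UTR: segments are taken
#' exactly as annotated. The result is invariant under segment order and
#' strand.
#'
#' @param ann A [genome_annotation].
#' @return Tibble with columns `transcript_id`, `gene_id`, `utr3_len`, one row
#'   per transcript in the annotation.
#' @export
utr3_lengths <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  tx <- ann_transcripts(ann) |> select("transcript_id", "gene_id")
  utr <- ann$features |>
    filter(.data$kind == "three_prime_utr", !is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(utr3_len = sum(.data$end - .data$start + 1L), .groups = "drop")
  tx |>
    left_join(utr, by = "transcript_id") |>
    mutate(utr3_len = dplyr::coalesce(.data$utr3_len, 0L))
}

#' 3' UTR length of a single transcript
#'
#' @param ann A [genome_annotation].
#' @param transcript_id Transcript ID present in `ann`.
#' @return Non-negative integer (nucleotides).
#' @export
utr3_length <- function(ann, transcript_id) {
  stopifnot(is_genome_annotation(ann))
  seg <- ann$features |>
    filter(.data$transcript_id == !!transcript_id,
           .data$kind == "three_prime_utr")
  sum(seg$end - seg$start + 1L)
}

#' Derive 3' UTR segments from CDS and stop codon
#'
#' For GTF dialects lacking explicit `three_prime_utr` lines, derives them as
#' the exonic sequence strictly 3' of the stop codon: on the plus strand, the
#' exon portions downstream of the stop codon's last base; mirrored on the
#' minus strand. The stop codon itself is excluded. Transcripts already
#' carrying `three_prime_utr` segments are left unchanged (idempotent);
#' transcripts without a stop codon cannot be derived and are flagged.
#'
#' Off by default everywhere else in the package: completeness audits count
#' the features as written in column 3.
#'
#' @param ann A [genome_annotation].
#' @return A list with `annotation` (a [genome_annotation] with derived
#'   segments added) and `underivable` (tibble of transcripts with CDS but no
#'   stop codon, left unchanged).
#' @export
derive_utr3_from_cds <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  feats <- ann$features
  by_tx <- feats |>
    filter(!is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      has_utr3 = any(.data$kind == "three_prime_utr"),
      has_cds = any(.data$kind == "CDS"),
      has_stop = any(.data$kind == "stop_codon"),
      .groups = "drop"
    )
  todo <- by_tx |> filter(.data$has_cds, !.data$has_utr3, .data$has_stop)
  underivable <- by_tx |>
    filter(.data$has_cds, !.data$has_utr3, !.data$has_stop) |>
    select("transcript_id", "gene_id") |>
    mutate(reason = "no stop_codon segment")

  if (nrow(todo) == 0) {
    return(list(annotation = ann, underivable = underivable))
  }

  tx_feats <- feats |>
    filter(.data$transcript_id %in% todo$transcript_id)
  derived <- tx_feats |>
    group_by(.data$transcript_id) |>
    group_modify(function(df, key) derive_one_utr3(df)) |>
    ungroup()

  out <- bind_rows(feats, derived[, .feature_cols])
  list(
    annotation = genome_annotation(out, label = ann$label),
    underivable = underivable
  )
}

# df: all feature rows of one transcript. Returns derived three_prime_utr rows
# (possibly 0 rows). The 3' side of the stop codon is intersected with exons.
derive_one_utr3 <- function(df) {
  ex <- df |> filter(.data$kind == "exon")
  stop_seg <- df |> filter(.data$kind == "stop_codon")
  strand <- ex$strand[1]
  if (strand == "+") {
    lo <- max(stop_seg$end) + 1L
    hi <- max(ex$end)
  } else {
    lo <- min(ex$start)
    hi <- min(stop_seg$start) - 1L
  }
  if (lo > hi) return(df[0, ])
  utr <- ex |>
    mutate(start = pmax(.data$start, lo), end = pmin(.data$end, hi)) |>
    filter(.data$start <= .data$end) |>
    mutate(feature = "three_prime_utr", kind = "three_prime_utr",
           frame = ".")
  utr
}
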