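#' Terminal 3' UTR exons of an annotation
#'
#' For every transcript with a nonzero 3' UTR, locates the 3'-most exon
#' containing 3' UTR sequence and records its matching anchor: the 5'
#' boundary of that exon, i.e. the exon start on the plus strand and the exon
#' end on the minus strand. That anchor is the coordinate on which genes are
#' matched across annotations, because it is stable even when two annotations
#' disagree about how far the 3' UTR extends.
#'
#' @param ann A [genome_annotation].
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (the terminal UTR exon), `anchor`, `utr3_len`.
#' @export
terminal_utr_exons <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  lens <- utr3_lengths(ann) |> filter(.data$utr3_len > 0)
  if (nrow(lens) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      anchor = integer(), utr3_len = integer()
    ))
  }
  uspan <- ann$features |>
    filter(.data$kind == "three_prime_utr", !is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(u_lo = min(.data$start), u_hi = max(.data$end),
              .groups = "drop")
  ex <- ann_exons(ann) |>
    inner_join(uspan, by = "transcript_id") |>
    filter(.data$end >= .data$u_lo, .data$start <= .data$u_hi) |>
    # the 3'-most candidate: largest start on "+", smallest on "-"
    mutate(.key = ifelse(.data$strand == "+", -.data$start, .data$start)) |>
    arrange(.data$transcript_id, .data$.key) |>
    distinct(.data$transcript_id, .keep_all = TRUE) |>
    select(-".key")
  ex |>
    inner_join(lens |> select("transcript_id", "utr3_len"),
               by = "transcript_id") |>
    mutate(anchor = ifelse(.data$strand == "+", .data$start, .data$end)) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "anchor", "utr3_len")
}

#' Representative transcript per gene (longest 3' UTR)
#'
#' Picks, for each gene, the single transcript with the longest annotated 3'
#' UTR; ties go to the lexicographically smallest transcript ID. Genes with no
#' UTR-bearing transcript are excluded (they cannot take part in 3' UTR length
#' comparisons) and listed in the `excluded` attribute of the result.
#'
#' @param ann A [genome_annotation].
#' @return Tibble `gene_id`, `transcript_id`, `utr3_len`; attribute
#'   `excluded` holds gene IDs with no UTR-bearing transcript.
#' @export
representative_transcripts <- function(ann) {
  lens <- utr3_lengths(ann)
  rep <- lens |>
    filter(.data$utr3_len > 0) |>
    arrange(.data$gene_id, dplyr::desc(.data$utr3_len),
            .data$transcript_id) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "transcript_id", "utr3_len")
  attr(rep, "excluded") <- setdiff(unique(lens$gene_id), rep$gene_id)
  rep
}

#' Collapse terminal UTR exons with identical coordinates
#'
#' Entries sharing (chrom, strand, start, end) are merged into one; the
#' surviving transcript ID is the lexicographically smallest among the
#' duplicates, and the longest 3' UTR among them is retained. Deterministic
#' replacement for an arbitrary choice among duplicates.
#'
#' @param exons Tibble as returned by [terminal_utr_exons()].
#' @return Tibble of the same shape with duplicates collapsed.
#' @export
collapse_terminal_exons <- function(exons) {
  exons |>
    group_by(.data$chrom, .data$strand, .data$start, .data$end) |>
    arrange(.data$transcript_id, .by_group = TRUE) |>
    summarise(
      transcript_id = .data$transcript_id[1],
      gene_id = .data$gene_id[1],
      anchor = .data$anchor[1],
      utr3_len = max(.data$utr3_len),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "anchor", "utr3_len")
}

#' Classify relative 3' UTR length
#'
#' "Longer" means more than `threshold` nucleotides longer: a delta of exactly
#' `threshold` is still "same".
#'
#' @param len_a,len_b Non-negative UTR lengths (nt); vectorized.
#' @param threshold Nucleotide difference that must be exceeded (default 50).
#' @return Character vector in `{"same", "longer_A", "longer_B"}`.
#' @export
classify_relative_length <- function(len_a, len_b, threshold = 50) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  dplyr::case_when(
    len_a - len_b > threshold ~ "longer_A",
    len_b - len_a > threshold ~ "longer_B",
    TRUE ~ "same"
  )
}

#' Build a matched reference gene set across two annotations
#'
#' For each gene of the driver annotation `ann_a`, its representative
#' transcript (longest 3' UTR) contributes a terminal-UTR-exon anchor; that
#' anchor is matched by exact (chrom, strand, position) equality against the
#' collapsed terminal-UTR-exon anchors of `ann_b`. Matched genes form the
#' reference set; unmatched genes are excluded. When several `ann_b` entries
#' share one anchor, the entry with the longest 3' UTR is paired and the row
#' is flagged ambiguous.
#'
#' @param ann_a Driver annotation (its gene IDs key the rows).
#' @param ann_b Annotation to match against.
#' @param threshold Passed to [classify_relative_length()].
#' @return A `utr_refset` tibble: `gene_key`, `rep_transcript_A`,
#'   `rep_transcript_B`, `utr3_len_A`, `utr3_len_B`, `class_AB`,
#'   `ambiguous_B`, plus the anchor columns `chrom`, `strand`, `anchor` used
#'   for downstream incorporation.
#' @examples
#' sim <- simulate_annotations(fixture_config(n_genes = 30, seed = 2))
#' rs <- build_reference_set(sim$annA, sim$annB)
#' table(rs$class_AB)
#' @export
build_reference_set <- function(ann_a, ann_b, threshold = 50) {
  rep_a <- representative_transcripts(ann_a)
  term_a <- terminal_utr_exons(ann_a) |>
    semi_join(rep_a, by = c("gene_id", "transcript_id"))
  term_b <- collapse_terminal_exons(terminal_utr_exons(ann_b))

  dup_anchor <- term_b |>
    count(.data$chrom, .data$strand, .data$anchor) |>
    filter(.data$n > 1L)
  b_by_anchor <- term_b |>
    arrange(.data$chrom, .data$strand, .data$anchor,
            dplyr::desc(.data$utr3_len), .data$transcript_id) |>
    distinct(.data$chrom, .data$strand, .data$anchor, .keep_all = TRUE) |>
    left_join(dup_anchor, by = c("chrom", "strand", "anchor")) |>
    transmute(
      .data$chrom, .data$strand, .data$anchor,
      rep_transcript_B = .data$transcript_id,
      gene_id_B = .data$gene_id,
      utr3_len_B = .data$utr3_len,
      ambiguous_B = !is.na(.data$n)
    )

  rows <- term_a |>
    inner_join(b_by_anchor, by = c("chrom", "strand", "anchor")) |>
    transmute(
      gene_key = .data$gene_id,
      rep_transcript_A = .data$transcript_id,
      rep_transcript_B = .data$rep_transcript_B,
      gene_id_B = .data$gene_id_B,
      utr3_len_A = .data$utr3_len,
      utr3_len_B = .data$utr3_len_B,
      class_AB = classify_relative_length(.data$utr3_len,
                                          .data$utr3_len_B, threshold),
      ambiguous_B = .data$ambiguous_B,
      chrom = .data$chrom,
      strand = .data$strand,
      anchor = .data$anchor
    ) |>
    arrange(.data$gene_key)
  class(rows) <- c("utr_refset", class(rows))
  attr(rows, "threshold") <- threshold
  rows
}

#' Incorporate a third annotation into a reference set
#'
#' Matches genes of `ann_c` onto existing reference-set rows by the same
#' terminal-exon anchor key, then classifies each matched gene's 3' UTR length
#' against the longer of the two lengths already in the row: `longer_C` when
#' it exceeds `max(len_A, len_B)` by more than the threshold, `shorter_C` when
#' it falls short by more than the threshold, else `same`. Rows with no match
#' in `ann_c` get `NA` length and class.
#'
#' @param refset Result of [build_reference_set()].
#' @param ann_c A [genome_annotation].
#' @param threshold Nucleotide threshold; defaults to the one stored in
#'   `refset`.
#' @return `refset` with added columns `rep_transcript_C`, `utr3_len_C`,
#'   `class_C`.
#' @export
incorporate_annotation <- function(refset, ann_c,
                                   threshold = attr(refset, "threshold") %||% 50) {
  term_c <- collapse_terminal_exons(terminal_utr_exons(ann_c)) |>
    arrange(.data$chrom, .data$strand, .data$anchor,
            dplyr::desc(.data$utr3_len), .data$transcript_id) |>
    distinct(.data$chrom, .data$strand, .data$anchor, .keep_all = TRUE) |>
    select("chrom", "strand", "anchor",
           rep_transcript_C = "transcript_id", utr3_len_C = "utr3_len")
  out <- refset |>
    left_join(term_c, by = c("chrom", "strand", "anchor")) |>
    mutate(
      best_AB = pmax(.data$utr3_len_A, .data$utr3_len_B),
      class_C = dplyr::case_when(
        is.na(.data$utr3_len_C) ~ NA_character_,
        .data$utr3_len_C - .data$best_AB > threshold ~ "longer_C",
        .data$best_AB - .data$utr3_len_C > threshold ~ "shorter_C",
        TRUE ~ "same"
      )
    ) |>
    select(-"best_AB")
  class(out) <- c("utr_refset", setdiff(class(out), "utr_refset"))
  attr(out, "threshold") <- attr(refset, "threshold") %||% threshold
  out
}

#' Write a reference set as TSV
#'
#' @param refset A `utr_refset`.
#' @param path Output path.
#' @export
write_reference_set <- function(refset, path) {
  readr::write_tsv(as_tibble(refset), path, progress = FALSE)
  invisible(path)
}

#' @method glance utr_refset
#' @export
glance.utr_refset <- function(x, ...) {
  out <- tibble(
    n_genes = nrow(x),
    n_same = sum(x$class_AB == "same"),
    n_longer_A = sum(x$class_AB == "longer_A"),
    n_longer_B = sum(x$class_AB == "longer_B")
  )
  if ("class_C" %in% names(x)) {
    out$n_matched_C <- sum(!is.na(x$class_C))
    out$n_longer_C <- sum(x$class_C == "longer_C", na.rm = TRUE)
  }
  out
}

#' @method autoplot utr_refset
#' @export
autoplot.utr_refset <- function(object, ...) {
  df <- as_tibble(object) |> count(.data$class_AB)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$n,
                                   fill = .data$class_AB)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(title = "Relative 3' UTR length in reference genes",
                  x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_void()
}
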