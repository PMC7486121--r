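#' Intron chain of every transcript
#'
#' The intron chain is the ordered list of splice junctions
#' `(donor = exon_i end, acceptor = exon_{i+1} start)` over consecutive exons
#' in genomic order; it is empty for single-exon transcripts. Two transcripts
#' with identical chains are structurally "the same" irrespective of terminal
#' exon boundary differences.
#'
#' @param ann A [genome_annotation].
#' @return Tibble `transcript_id`, `gene_id`, `chrom`, `strand`, `donor`,
#'   `acceptor`, one row per junction (transcripts with no junctions are
#'   absent).
#' @export
intron_chains <- function(ann) {
  ex <- ann_exons(ann) |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(donor = .data$end, acceptor = dplyr::lead(.data$start)) |>
    filter(!is.na(.data$acceptor)) |>
    ungroup()
  ex |> select("transcript_id", "gene_id", "chrom", "strand",
               "donor", "acceptor")
}

# Per-transcript summary used by the pairwise classifier: exon count, span,
# total exonic length, chain string "donor:acceptor|..." ("" if single-exon).
transcript_structures <- function(ann) {
  ex <- ann_exons(ann)
  if (nrow(ex) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), n_exons = integer(), exonic_len = integer(),
      chain = character()
    ))
  }
  chains <- intron_chains(ann) |>
    group_by(.data$transcript_id) |>
    summarise(
      chain = paste(paste0(.data$donor, ":", .data$acceptor), collapse = "|"),
      .groups = "drop"
    )
  ex |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_exons = dplyr::n(),
      exonic_len = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    ) |>
    left_join(chains, by = "transcript_id") |>
    mutate(chain = dplyr::coalesce(.data$chain, ""))
}

#' Classify a query transcript against a reference transcript
#'
#' gffcompare-style structural class codes:
#' \describe{
#'   \item{`=` (full match)}{identical intron chains for multi-exon pairs
#'     (terminal exon outer boundaries may differ); for two single-exon
#'     transcripts, reciprocal exonic overlap of at least
#'     `single_exon_frac` of the shorter one.}
#'   \item{`c` (contained)}{the query's chain is a contiguous sub-chain of
#'     the reference's; a single-exon query lying entirely within a
#'     reference exon.}
#'   \item{`j`}{at least one shared splice junction, but not `=`/`c`.}
#'   \item{`o`}{same-strand exonic overlap without any shared junction.}
#'   \item{`x`}{exonic overlap on the opposite strand only.}
#'   \item{`u`}{no exonic overlap (or different chromosome).}
#' }
#' Features with strand `.` are compared against both strands but can never
#' yield `=`.
#'
#' @param query,reference [genome_annotation]s holding the two transcripts.
#' @param query_tx,reference_tx Transcript IDs.
#' @param single_exon_frac Reciprocal-overlap fraction (of the shorter
#'   transcript) required for a single-exon full match; default 0.8.
#' @return Single class-code string.
#' @export
classify_pair <- function(query, reference, query_tx, reference_tx,
                          single_exon_frac = 0.8) {
  q <- ann_keep_transcripts(query, query_tx)
  r <- ann_keep_transcripts(reference, reference_tx)
  pairs <- classify_candidate_pairs(transcript_structures(q),
                                    transcript_structures(r),
                                    ann_exons(q), ann_exons(r),
                                    single_exon_frac)
  if (nrow(pairs) == 0) "u" else pairs$class[1]
}

# Subset an annotation to given transcripts (keeps their gene-level rows).
ann_keep_transcripts <- function(ann, transcript_ids) {
  genome_annotation(
    ann$features |> filter(.data$transcript_id %in% transcript_ids),
    label = ann$label
  )
}

# Vectorized pairwise classification of all exon-overlapping (query,
# reference) transcript pairs. Returns one row per overlapping pair with its
# class code and overlap statistics; non-overlapping pairs are absent
# (class "u" is decided by the caller).
classify_candidate_pairs <- function(qs, rs, qex, rex, single_exon_frac) {
  empty <- tibble(
    reference_tx = character(), query_tx = character(),
    class = character(), overlap_bp = integer(), same_strand = logical()
  )
  if (nrow(qex) == 0 || nrow(rex) == 0) return(empty)
  qgr <- exons_as_granges(qex)
  rgr <- exons_as_granges(rex)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = TRUE)
  )
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  ov <- tibble(
    query_tx = qex$transcript_id[qi],
    reference_tx = rex$transcript_id[ri],
    q_strand = qex$strand[qi],
    r_strand = rex$strand[ri],
    ov_bp = pmin(qex$end[qi], rex$end[ri]) -
      pmax(qex$start[qi], rex$start[ri]) + 1L,
    q_in_r = qex$start[qi] >= rex$start[ri] & qex$end[qi] <= rex$end[ri]
  )
  strand_compat <- ov$q_strand == ov$r_strand |
    ov$q_strand == "." | ov$r_strand == "."
  pair_ov <- ov |>
    mutate(same_strand = strand_compat) |>
    group_by(.data$query_tx, .data$reference_tx) |>
    summarise(
      same_strand = .data$same_strand[1],
      overlap_bp = sum(.data$ov_bp),
      q_exon_contained = any(.data$q_in_r),
      .groups = "drop"
    )

  # shared junction counts (same-strand by construction of the join)
  qj <- junctions_of(qex)
  rj <- junctions_of(rex)
  shared <- if (nrow(qj) > 0 && nrow(rj) > 0) {
    inner_join(qj, rj, by = c("chrom", "donor", "acceptor"),
               relationship = "many-to-many") |>
      filter(.data$strand.x == .data$strand.y |
               .data$strand.x == "." | .data$strand.y == ".") |>
      count(query_tx = .data$transcript_id.x,
            reference_tx = .data$transcript_id.y, name = "n_shared_junc")
  } else {
    tibble(query_tx = character(), reference_tx = character(),
           n_shared_junc = integer())
  }

  pair_ov |>
    left_join(shared, by = c("query_tx", "reference_tx")) |>
    mutate(n_shared_junc = dplyr::coalesce(.data$n_shared_junc, 0L)) |>
    left_join(qs |> select(query_tx = "transcript_id", q_chain = "chain",
                           q_nex = "n_exons", q_len = "exonic_len",
                           q_str = "strand"),
              by = "query_tx") |>
    left_join(rs |> select(reference_tx = "transcript_id",
                           r_chain = "chain", r_nex = "n_exons",
                           r_len = "exonic_len", r_str = "strand"),
              by = "reference_tx") |>
    mutate(
      dotted = .data$q_str == "." | .data$r_str == ".",
      full = .data$same_strand & !.data$dotted & (
        (.data$q_nex > 1L & .data$r_nex > 1L &
           .data$q_chain == .data$r_chain) |
          (.data$q_nex == 1L & .data$r_nex == 1L &
             .data$overlap_bp >=
               single_exon_frac * pmin(.data$q_len, .data$r_len))
      ),
      contained = .data$same_strand & !.data$full & (
        (.data$q_nex > 1L & .data$r_nex > 1L &
           .data$q_chain != .data$r_chain &
           stringr::str_detect(
             paste0("|", .data$r_chain, "|"),
             stringr::fixed(paste0("|", .data$q_chain, "|"))
           )) |
          (.data$q_nex == 1L & .data$q_exon_contained)
      ),
      class = dplyr::case_when(
        !same_strand ~ "x",
        full ~ "=",
        contained ~ "c",
        n_shared_junc >= 1L ~ "j",
        TRUE ~ "o"
      )
    ) |>
    select("reference_tx", "query_tx", "class", "overlap_bp", "same_strand")
}

junctions_of <- function(ex) {
  ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(chrom = .data$chrom, strand = .data$strand,
           donor = .data$end, acceptor = dplyr::lead(.data$start)) |>
    filter(!is.na(.data$acceptor)) |>
    ungroup() |>
    select("transcript_id", "chrom", "strand", "donor", "acceptor")
}

.class_priority <- c("=" = 1L, "c" = 2L, "j" = 3L, "o" = 4L, "x" = 5L,
                     "u" = 6L)

#' Match two annotations transcript-by-transcript
#'
#' Every reference transcript is assigned the best structural class among all
#' query transcripts sharing its locus (priority `=` > `c` > `j` > `o` > `x`;
#' `u` when nothing overlaps). Ties between query transcripts of the same
#' class are broken by larger exonic overlap, then by smaller transcript ID.
#' Gene-level rollups - matched gene pairs with a confidence note and the
#' provisional missing-gene list - are derived from the per-transcript table.
#'
#' @param query,reference [genome_annotation]s sharing a chromosome
#'   namespace.
#' @param single_exon_frac See [classify_pair()].
#' @return A `match_report`: list with `transcripts` (per reference
#'   transcript: `reference_tx`, `reference_gene`, `query_tx`, `query_gene`,
#'   `class`, `overlap_bp`), `gene_pairs` (`reference_gene`, `query_gene`,
#'   `confidence` in `{transcript_match, coordinate_overlap}`), and
#'   `missing_genes` (reference genes whose transcripts all have class `x` or
#'   `u`, see [confirm_missing_genes()]).
#' @examples
#' sim <- simulate_annotations(fixture_config(n_genes = 25, seed = 3))
#' rep <- match_annotations(sim$annA, sim$annB)
#' head(rep$missing_genes)
#' @export
match_annotations <- function(query, reference, single_exon_frac = 0.8) {
  qs <- transcript_structures(query)
  rs <- transcript_structures(reference)
  pairs <- classify_candidate_pairs(qs, rs, ann_exons(query),
                                    ann_exons(reference), single_exon_frac)
  best <- pairs |>
    mutate(prio = .class_priority[.data$class]) |>
    arrange(.data$reference_tx, .data$prio, dplyr::desc(.data$overlap_bp),
            .data$query_tx) |>
    distinct(.data$reference_tx, .keep_all = TRUE)
  transcripts <- rs |>
    select(reference_tx = "transcript_id", reference_gene = "gene_id") |>
    left_join(best |> select("reference_tx", query_tx = "query_tx",
                             "class", "overlap_bp"),
              by = "reference_tx") |>
    mutate(
      class = dplyr::coalesce(.data$class, "u"),
      overlap_bp = dplyr::coalesce(.data$overlap_bp, 0L)
    ) |>
    left_join(qs |> select(query_tx = "transcript_id",
                           query_gene = "gene_id"),
              by = "query_tx") |>
    select("reference_tx", "reference_gene", "query_tx", "query_gene",
           "class", "overlap_bp") |>
    arrange(.data$reference_tx)

  gene_pairs <- transcripts |>
    filter(.data$class %in% c("=", "c", "j", "o")) |>
    mutate(prio = .class_priority[.data$class]) |>
    arrange(.data$reference_gene, .data$prio, dplyr::desc(.data$overlap_bp),
            .data$query_tx) |>
    distinct(.data$reference_gene, .keep_all = TRUE) |>
    transmute(
      reference_gene = .data$reference_gene,
      query_gene = .data$query_gene,
      confidence = ifelse(.data$class == "=", "transcript_match",
                          "coordinate_overlap")
    )

  report <- structure(
    list(
      query_label = query$label,
      reference_label = reference$label,
      transcripts = transcripts,
      gene_pairs = gene_pairs,
      missing_genes = character(0)
    ),
    class = "match_report"
  )
  report$missing_genes <- confirm_missing_genes(report)
  report
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> query = %s, reference = %s\n",
              x$query_label, x$reference_label))
  print(table(x$transcripts$class))
  cat(sprintf("confirmed missing reference genes: %d\n",
              length(x$missing_genes)))
  invisible(x)
}

#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) x$transcripts

#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  cls <- table(factor(x$transcripts$class, levels = names(.class_priority)))
  tibble(
    query = x$query_label,
    reference = x$reference_label,
    n_reference_tx = nrow(x$transcripts),
    n_full = unname(cls["="]),
    n_contained = unname(cls["c"]),
    n_junction = unname(cls["j"]),
    n_exonic = unname(cls["o"]),
    n_antisense = unname(cls["x"]),
    n_unmatched = unname(cls["u"]),
    n_missing_genes = length(x$missing_genes)
  )
}

#' @method autoplot match_report
#' @export
autoplot.match_report <- function(object, ...) {
  df <- object$transcripts |>
    count(class = factor(.data$class, levels = names(.class_priority)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      title = sprintf("Structural classes: %s vs reference %s",
                      object$query_label, object$reference_label),
      x = "class code", y = "reference transcripts"
    ) +
    ggplot2::theme_minimal()
}

#' Confirm genes missing from the query annotation
#'
#' A reference gene is confirmed missing only when every one of its
#' transcripts has class `x` (antisense) or `u` (no overlap): any same-strand
#' overlap by any transcript anywhere in the gene rescues it. This mirrors
#' re-searching the reference for gene IDs matching each unmatched
#' transcript, so that a gene with one matched and one unmatched isoform is
#' not declared missing.
#'
#' @param report A `match_report`.
#' @return Character vector of confirmed-missing reference gene IDs, sorted.
#' @export
confirm_missing_genes <- function(report) {
  stopifnot(inherits(report, "match_report"))
  report$transcripts |>
    group_by(.data$reference_gene) |>
    summarise(missing = all(.data$class %in% c("x", "u")),
              .groups = "drop") |>
    filter(.data$missing) |>
    pull("reference_gene") |>
    sort()
}

#' Intersect two gene sets through an ID crosswalk
#'
#' Maps both sets into a shared ID namespace (e.g. NCBI gene IDs) and returns
#' the disjoint partition of the mapped union. IDs with no crosswalk entry are
#' excluded and counted. A source ID mapping to several shared IDs triggers an
#' ambiguity warning listing the duplicates; the first target in sort order is
#' kept.
#'
#' @param set_a,set_b Character vectors of gene IDs.
#' @param crosswalk Data frame with columns `gene_id`, `shared_id` covering
#'   IDs from both sets.
#' @return List with `a_only`, `b_only`, `both` (shared-ID character
#'   vectors) and `n_unmapped_a`, `n_unmapped_b`.
#' @export
intersect_gene_sets <- function(set_a, set_b, crosswalk) {
  stopifnot(all(c("gene_id", "shared_id") %in% names(crosswalk)))
  dup <- crosswalk |>
    distinct(.data$gene_id, .data$shared_id) |>
    count(.data$gene_id) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    warn(paste0("crosswalk maps ", nrow(dup),
                " gene ID(s) to multiple shared IDs; keeping first by sort: ",
                paste(head(dup$gene_id, 5), collapse = ", ")))
  }
  map <- crosswalk |>
    arrange(.data$gene_id, .data$shared_id) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  lk <- stats::setNames(map$shared_id, map$gene_id)
  ma <- unname(lk[set_a])
  mb <- unname(lk[set_b])
  a_ids <- unique(ma[!is.na(ma)])
  b_ids <- unique(mb[!is.na(mb)])
  list(
    a_only = sort(setdiff(a_ids, b_ids)),
    b_only = sort(setdiff(b_ids, a_ids)),
    both = sort(intersect(a_ids, b_ids)),
    n_unmapped_a = sum(is.na(ma)),
    n_unmapped_b = sum(is.na(mb))
  )
}
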