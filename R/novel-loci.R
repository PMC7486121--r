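#' Triage novel (XLOC) loci for retention
#'
#' Novel loci produced by assembly merging (gene IDs prefixed `XLOC`) are
#' kept, dropped, or declared redundant:
#' \itemize{
#'   \item \strong{redundant} - any transcript of the locus has class `=` or
#'     `c` (same strand) against a reference annotation: the locus merely
#'     duplicates an existing gene model.
#'   \item \strong{retain} - otherwise, if at least one criterion holds:
#'     (1) a protein-homology hit of `exact`, `high` or `moderate` confidence
#'     against a zebrafish or human protein (`low` fails the criterion);
#'     (2) matched or overlapping intron-exon structure with a published
#'     lincRNA set (class `=`, `c`, `j` or `o`); or
#'     (3) more than one exon in at least one transcript.
#'   \item \strong{drop} - single-exon loci with no supporting evidence.
#' }
#'
#' @param ann A [genome_annotation] containing XLOC genes.
#' @param evidence Data frame with columns `xloc_id`,
#'   `protein_hit_confidence` (`exact`/`high`/`moderate`/`low`/`none`) and
#'   optionally `species_hit`; one row per locus. Rows naming unknown loci
#'   trigger a warning. May be `NULL`.
#' @param lincrnas Optional [genome_annotation] of published lincRNA models.
#' @param refs List of reference [genome_annotation]s used for the redundancy
#'   check.
#' @param single_exon_frac Passed to the structural matcher.
#' @return Tibble `xloc_id`, `decision` (`retain`/`drop`/`redundant`),
#'   `reason`.
#' @examples
#' sim <- simulate_annotations(fixture_config(n_genes = 20, seed = 4,
#'                                            n_xloc = c(single_exon_no_evidence = 2,
#'                                                       multi_exon = 2)))
#' classify_xloc(sim$merged, sim$evidence, sim$lincrnas,
#'               list(A = sim$annA, B = sim$annB))
#' @export
classify_xloc <- function(ann, evidence = NULL, lincrnas = NULL, refs = list(),
                          single_exon_frac = 0.8) {
  stopifnot(is_genome_annotation(ann))
  if (is_genome_annotation(refs)) refs <- list(refs)
  genes <- ann_genes(ann)
  xloc_ids <- genes$gene_id[startsWith(genes$gene_id, "XLOC")]
  if (length(xloc_ids) == 0) {
    return(tibble(xloc_id = character(), decision = character(),
                  reason = character()))
  }
  xloc_ann <- ann_keep_genes(ann, xloc_ids)
  xtx <- ann_transcripts(xloc_ann)

  if (!is.null(evidence)) {
    stopifnot(all(c("xloc_id", "protein_hit_confidence") %in% names(evidence)))
    unknown <- setdiff(evidence$xloc_id, xloc_ids)
    if (length(unknown) > 0) {
      warn(paste0("evidence rows for unknown XLOC ID(s): ",
                  paste(head(unknown, 5), collapse = ", ")))
    }
  }

  # structural classes of each XLOC gene's transcripts (as query) against the
  # other annotation; only overlap-producing classes appear
  xstr <- transcript_structures(xloc_ann)
  xex <- ann_exons(xloc_ann)
  gene_of_tx <- stats::setNames(xstr$gene_id, xstr$transcript_id)
  best_class_vs <- function(other) {
    pairs <- classify_candidate_pairs(xstr, transcript_structures(other),
                                      xex, ann_exons(other),
                                      single_exon_frac)
    pairs |>
      mutate(gene_id = unname(gene_of_tx[.data$query_tx])) |>
      group_by(.data$gene_id) |>
      summarise(classes = list(unique(.data$class)), .groups = "drop")
  }
  ref_classes <- purrr::map(refs, best_class_vs)
  redundant <- unique(unlist(purrr::map(ref_classes, function(tc) {
    tc$gene_id[purrr::map_lgl(tc$classes, ~ any(.x %in% c("=", "c")))]
  })))

  linc_hit <- character(0)
  if (!is.null(lincrnas)) {
    lc <- best_class_vs(lincrnas)
    linc_hit <- lc$gene_id[purrr::map_lgl(lc$classes,
                                          ~ any(.x %in% c("=", "c", "j", "o")))]
  }

  conf <- rep(NA_character_, length(xloc_ids))
  names(conf) <- xloc_ids
  if (!is.null(evidence)) {
    ev <- evidence |>
      filter(.data$xloc_id %in% xloc_ids) |>
      distinct(.data$xloc_id, .keep_all = TRUE)
    conf[ev$xloc_id] <- ev$protein_hit_confidence
  }
  max_exons <- xtx |>
    group_by(.data$gene_id) |>
    summarise(mx = max(.data$n_exons), .groups = "drop")
  mx <- stats::setNames(max_exons$mx, max_exons$gene_id)[xloc_ids]
  mx[is.na(mx)] <- 1L

  tibble(xloc_id = sort(xloc_ids)) |>
    mutate(
      is_redundant = .data$xloc_id %in% redundant,
      has_protein = dplyr::coalesce(
        conf[.data$xloc_id] %in% c("exact", "high", "moderate"), FALSE),
      has_lincrna = .data$xloc_id %in% linc_hit,
      multi_exon = unname(mx[.data$xloc_id]) > 1L,
      decision = dplyr::case_when(
        is_redundant ~ "redundant",
        has_protein | has_lincrna | multi_exon ~ "retain",
        TRUE ~ "drop"
      ),
      reason = dplyr::case_when(
        is_redundant ~ "contained in reference transcript",
        has_protein ~ "protein homology",
        has_lincrna ~ "lincRNA structure match",
        multi_exon ~ "multi-exon",
        TRUE ~ "single exon, no evidence"
      )
    ) |>
    select("xloc_id", "decision", "reason")
}
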