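#' Detect spurious fusion transcripts in a merged annotation
#'
#' Assembly merging can produce transcripts whose exons span two or more
#' adjacent genes on one strand; these corrupt gene-level quantification and
#' cause nomenclature conflicts. A transcript is flagged when, within any
#' single reference annotation, its exons overlap exons of two or more
#' distinct same-strand reference genes, each by at least `min_overlap_bp`.
#' Reference genes merged under one ID count once.
#'
#' @param merged A [genome_annotation] (the assembly-merged annotation).
#' @param refs List of reference [genome_annotation]s.
#' @param min_overlap_bp Minimum per-gene exonic overlap (default 30 nt).
#' @return Tibble of fusion flags: `transcript_id`, `gene_id`, `ref_label`,
#'   `overlapped_gene_ids` (comma-separated), `n_genes`, `overlap_bp`
#'   (comma-separated, parallel to the gene list).
#' @export
detect_fusion_transcripts <- function(merged, refs, min_overlap_bp = 30) {
  stopifnot(is_genome_annotation(merged))
  if (is_genome_annotation(refs)) refs <- list(refs)
  mex <- ann_exons(merged)
  flags <- purrr::map(refs, function(ref) {
    rex <- ann_exons(ref)
    if (nrow(mex) == 0 || nrow(rex) == 0) return(NULL)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(exons_as_granges(mex), exons_as_granges(rex),
                                  ignore.strand = TRUE)
    )
    if (length(hits) == 0) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    tibble(
      transcript_id = mex$transcript_id[qi],
      gene_id = mex$gene_id[qi],
      ref_gene = rex$gene_id[ri],
      same_strand = mex$strand[qi] == rex$strand[ri],
      ov_bp = pmin(mex$end[qi], rex$end[ri]) -
        pmax(mex$start[qi], rex$start[ri]) + 1L
    ) |>
      filter(.data$same_strand) |>
      group_by(.data$transcript_id, .data$gene_id, .data$ref_gene) |>
      summarise(ov_bp = sum(.data$ov_bp), .groups = "drop") |>
      filter(.data$ov_bp >= min_overlap_bp) |>
      group_by(.data$transcript_id, .data$gene_id) |>
      filter(dplyr::n_distinct(.data$ref_gene) >= 2L) |>
      arrange(dplyr::desc(.data$ov_bp), .data$ref_gene, .by_group = TRUE) |>
      summarise(
        ref_label = ref$label,
        overlapped_gene_ids = paste(.data$ref_gene, collapse = ","),
        n_genes = dplyr::n_distinct(.data$ref_gene),
        overlap_bp = paste(.data$ov_bp, collapse = ","),
        .groups = "drop"
      )
  })
  out <- bind_rows(flags)
  if (nrow(out) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      ref_label = character(), overlapped_gene_ids = character(),
      n_genes = integer(), overlap_bp = character()
    ))
  }
  # one row per transcript: keep the reference seeing the most genes
  out |>
    group_by(.data$transcript_id) |>
    arrange(dplyr::desc(.data$n_genes), .data$ref_label, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$transcript_id)
}

#' Remove transcripts from an annotation
#'
#' Genes left with zero transcripts are removed too and reported.
#'
#' @param ann A [genome_annotation].
#' @param transcript_ids Transcript IDs to remove; unknown IDs are an error.
#' @return List with `annotation` (pruned) and `removed_genes` (gene IDs
#'   dropped because they lost their last transcript).
#' @export
remove_transcripts <- function(ann, transcript_ids) {
  stopifnot(is_genome_annotation(ann))
  transcript_ids <- unique(transcript_ids)
  known <- unique(ann$features$transcript_id)
  unknown <- setdiff(transcript_ids, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown transcript ID(s): ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  affected <- unique(ann$features$gene_id[
    !is.na(ann$features$transcript_id) &
      ann$features$transcript_id %in% transcript_ids])
  feats <- ann$features |>
    filter(is.na(.data$transcript_id) |
             !(.data$transcript_id %in% transcript_ids))
  still <- unique(feats$gene_id[!is.na(feats$transcript_id)])
  removed_genes <- setdiff(affected, still)
  feats <- feats |> filter(!(.data$gene_id %in% removed_genes))
  list(
    annotation = genome_annotation(feats, label = ann$label),
    removed_genes = sort(removed_genes)
  )
}

#' Remove small-RNA genes (but never miRNAs)
#'
#' Drops genes whose biotype is in `biotypes`. miRNA genes are always kept,
#' whatever the set contains. Annotations with no biotype labels are returned
#' unchanged with a warning.
#'
#' @param ann A [genome_annotation] with `gene_biotype` attributes.
#' @param biotypes Biotypes to remove.
#' @return List with `annotation` and `removed_genes`.
#' @export
remove_small_rna <- function(ann, biotypes = c("rRNA", "snRNA", "snoRNA",
                                               "sRNA", "miscRNA")) {
  stopifnot(is_genome_annotation(ann))
  if (length(biotypes) == 0) {
    return(list(annotation = ann, removed_genes = character(0)))
  }
  genes <- ann_genes(ann)
  if (all(is.na(genes$biotype))) {
    warn("annotation carries no biotype labels; nothing removed")
    return(list(annotation = ann, removed_genes = character(0)))
  }
  victims <- genes |>
    filter(.data$biotype %in% setdiff(biotypes, "miRNA")) |>
    pull("gene_id")
  list(
    annotation = ann_drop_genes(ann, victims),
    removed_genes = sort(victims)
  )
}

#' Assign gene nomenclature from reference annotations
#'
#' Symbols and names are imported by matched gene: a merged gene matched to a
#' gene of the primary reference (Ensembl-style) takes that symbol; failing
#' that, the secondary reference (RefSeq-style) symbol; failing both, a
#' placeholder `XLOC_<n>` novel-locus symbol. Conflicts are recorded, never
#' silently resolved: (a) one merged gene matching reference genes carrying
#' different symbols (the signature of a fusion or of a reference split
#' locus), and (b) one symbol landing on more than one merged locus.
#'
#' @param merged A [genome_annotation].
#' @param ens,refseq Reference [genome_annotation]s (symbol priority ens >
#'   refseq).
#' @param report_ens,report_refseq `match_report`s from
#'   `match_annotations(query = merged, reference = ens/refseq)`.
#' @return List with `annotation` (symbols written into `gene_name`
#'   attributes of every feature row), `assignments` (tibble `gene_id`,
#'   `symbol`, `source`), and `conflicts` (tibble `type`, `gene_id`,
#'   `symbol`, `detail`).
#' @export
assign_nomenclature <- function(merged, ens, refseq,
                                report_ens, report_refseq) {
  stopifnot(is_genome_annotation(merged))
  ens_sym <- ann_genes(ens) |> select("gene_id", "symbol")
  ref_sym <- ann_genes(refseq) |> select("gene_id", "symbol")

  # merged gene -> set of matched reference genes, per reference
  link <- function(report, sym_tbl, source) {
    report$transcripts |>
      filter(.data$class %in% c("=", "c", "j", "o"),
             !is.na(.data$query_gene)) |>
      distinct(gene_id = .data$query_gene, ref_gene = .data$reference_gene,
               .data$class, .data$overlap_bp) |>
      left_join(sym_tbl, by = c(ref_gene = "gene_id")) |>
      mutate(source = source)
  }
  links_e <- link(report_ens, ens_sym, "ensembl")
  links_r <- link(report_refseq, ref_sym, "refseq")

  multi <- bind_rows(links_e, links_r) |>
    filter(!is.na(.data$symbol)) |>
    group_by(.data$gene_id, .data$source) |>
    filter(dplyr::n_distinct(.data$symbol) > 1L) |>
    summarise(symbols = paste(sort(unique(.data$symbol)), collapse = ","),
              .groups = "drop")
  conflicts_a <- multi |>
    transmute(type = "multiple_reference_symbols",
              gene_id = .data$gene_id, symbol = .data$symbols,
              detail = paste0("reference: ", .data$source))

  pick <- function(links) {
    links |>
      filter(!is.na(.data$symbol)) |>
      mutate(prio = .class_priority[.data$class]) |>
      group_by(.data$gene_id) |>
      arrange(.data$prio, dplyr::desc(.data$overlap_bp), .data$symbol,
              .by_group = TRUE) |>
      summarise(symbol = .data$symbol[1], source = .data$source[1],
                .groups = "drop")
  }
  chosen <- bind_rows(pick(links_e), pick(links_r)) |>
    group_by(.data$gene_id) |>
    arrange(match(.data$source, c("ensembl", "refseq")), .by_group = TRUE) |>
    slice(1L) |>
    ungroup()

  all_genes <- ann_genes(merged) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  assignments <- all_genes |>
    select("gene_id") |>
    left_join(chosen, by = "gene_id")
  novel <- which(is.na(assignments$symbol))
  assignments$symbol[novel] <- sprintf("XLOC_%06d", seq_along(novel))
  assignments$source[novel] <- "novel"

  dup <- assignments |>
    count(.data$symbol) |>
    filter(.data$n > 1L)
  conflicts_b <- assignments |>
    semi_join(dup, by = "symbol") |>
    transmute(type = "symbol_on_multiple_loci", gene_id = .data$gene_id,
              symbol = .data$symbol, detail = "")

  feats <- merged$features
  sym_by_gene <- stats::setNames(assignments$symbol, assignments$gene_id)
  feats$attr_rest <- set_gtf_attr(feats$attr_rest, "gene_name",
                                  unname(sym_by_gene[feats$gene_id]))
  list(
    annotation = genome_annotation(feats, label = merged$label),
    assignments = assignments,
    conflicts = bind_rows(conflicts_a, conflicts_b) |>
      arrange(.data$type, .data$gene_id)
  )
}

#' Add confirmed-missing reference genes back into a curated annotation
#'
#' Each confirmed-missing gene's transcript models are copied in verbatim from
#' its reference annotation, tagged with a `match_note` attribute
#' (`added_back_<label>`). Genes split across chromosomes contribute only the
#' piece with the larger total exonic span; ties go to the piece containing
#' the 3' UTR. A gene whose exons would overlap an existing curated gene on
#' the same strand is skipped (so the add-back cannot re-create a fusion) and
#' reported.
#'
#' @param curated A [genome_annotation].
#' @param missing Named list: for each reference, the confirmed-missing gene
#'   IDs (from [confirm_missing_genes()]). Names must index `refs`.
#' @param refs Named list of reference [genome_annotation]s.
#' @return List with `annotation`, `added` (tibble `gene_id`, `ref`), and
#'   `skipped` (tibble `gene_id`, `ref`, `reason`).
#' @export
add_back_missing <- function(curated, missing, refs) {
  stopifnot(is_genome_annotation(curated))
  stopifnot(is.list(refs), !is.null(names(refs)))
  # grows as genes are added, so a gene added from one reference blocks the
  # same locus arriving again from another
  cur_ex <- ann_exons(curated) |>
    select("chrom", "start", "end", "strand", "gene_id")
  feats_out <- list(curated$features)
  added <- list()
  skipped <- list()

  for (ref_name in names(missing)) {
    ref <- refs[[ref_name]]
    if (is.null(ref)) abort(paste0("no reference named ", ref_name))
    ids <- missing[[ref_name]]
    if (length(ids) == 0) next
    note <- paste0("added_back_", ref_name)
    for (gid in sort(ids)) {
      g_feats <- ref$features |> filter(.data$gene_id == gid)
      if (nrow(g_feats) == 0) {
        skipped[[length(skipped) + 1L]] <-
          tibble(gene_id = gid, ref = ref_name, reason = "not in reference")
        next
      }
      g_feats <- pick_split_piece(g_feats)
      g_ex <- g_feats |> filter(.data$kind == "exon")
      coll <- character(0)
      for (r in seq_len(nrow(g_ex))) {
        near <- cur_ex |>
          filter(.data$chrom == g_ex$chrom[r],
                 .data$strand == g_ex$strand[r],
                 .data$start <= g_ex$end[r], .data$end >= g_ex$start[r])
        coll <- union(coll, near$gene_id)
      }
      if (length(coll) > 0) {
        skipped[[length(skipped) + 1L]] <- tibble(
          gene_id = gid, ref = ref_name,
          reason = paste0("same-strand overlap with curated gene(s): ",
                          paste(head(sort(coll), 3), collapse = ","))
        )
        next
      }
      g_feats$attr_rest <- set_gtf_attr(g_feats$attr_rest, "match_note", note)
      feats_out[[length(feats_out) + 1L]] <- g_feats
      added[[length(added) + 1L]] <- tibble(gene_id = gid, ref = ref_name)
      cur_ex <- bind_rows(
        cur_ex,
        g_ex |> select("chrom", "start", "end", "strand", "gene_id")
      )
    }
  }
  list(
    annotation = genome_annotation(bind_rows(feats_out),
                                   label = curated$label),
    added = if (length(added)) bind_rows(added)
            else tibble(gene_id = character(), ref = character()),
    skipped = if (length(skipped)) bind_rows(skipped)
              else tibble(gene_id = character(), ref = character(),
                          reason = character())
  )
}

# For a gene annotated on several chromosomes keep one piece: largest total
# exonic span; ties broken in favor of the piece carrying 3' UTR sequence,
# then by chromosome name.
pick_split_piece <- function(g_feats) {
  if (dplyr::n_distinct(g_feats$chrom) == 1L) return(g_feats)
  rank <- g_feats |>
    group_by(.data$chrom) |>
    summarise(
      span = sum((.data$end - .data$start + 1L)[.data$kind == "exon"]),
      has_utr3 = any(.data$kind == "three_prime_utr"),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$span), dplyr::desc(.data$has_utr3),
            .data$chrom)
  g_feats |> filter(.data$chrom == rank$chrom[1])
}

#' Assign stable LL gene identifiers
#'
#' Every gene receives a unique arbitrary identifier `LL1`, `LL2`, ... in
#' (chromosome, start, gene ID) sort order, which makes the assignment
#' deterministic across runs. The ID is written into every GTF line of the
#' gene as an `ll_id` attribute, linking the annotation to its
#' gene-information table.
#'
#' @param ann A [genome_annotation].
#' @return List with `annotation` (carrying `ll_id` attributes) and `table`
#'   (tibble `ll_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `symbol`).
#' @export
assign_ll_ids <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  genes <- ann_genes(ann) |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    mutate(ll_id = paste0("LL", dplyr::row_number()))
  feats <- ann$features
  ll_by_gene <- stats::setNames(genes$ll_id, genes$gene_id)
  feats$attr_rest <- set_gtf_attr(feats$attr_rest, "ll_id",
                                  unname(ll_by_gene[feats$gene_id]))
  list(
    annotation = genome_annotation(feats, label = ann$label),
    table = genes |> select("ll_id", "gene_id", "chrom", "start", "end",
                            "strand", "symbol")
  )
}

#' Build the curated gene-information table
#'
#' One record per gene: LL ID, external gene IDs imported through ID
#' crosswalks, symbol, name, and a match-confidence note saying how each
#' external link was established (`full_transcript_match` for an `=` class,
#' `gene_coordinate_overlap` otherwise, `added_back_*` for re-instated genes,
#' `novel_xloc` for XLOC loci with no external link).
#'
#' @param ann A [genome_annotation] carrying `ll_id` attributes (see
#'   [assign_ll_ids()]).
#' @param crosswalks Named list of data frames (`gene_id`, `external_id`),
#'   e.g. `list(ensembl = ..., ncbi = ..., zfin = ...)`, mapping curated gene
#'   IDs to external namespaces. May be empty.
#' @param report_ens,report_refseq Optional `match_report`s (query = curated
#'   annotation) used to derive the match-confidence note.
#' @return Tibble `ll_id`, `gene_id`, `ensembl_gene_id`, `ncbi_id`,
#'   `zfin_id`, `symbol`, `name`, `match_note`.
#' @export
build_gene_info <- function(ann, crosswalks = list(),
                            report_ens = NULL, report_refseq = NULL) {
  stopifnot(is_genome_annotation(ann))
  genes <- ann_genes(ann) |>
    left_join(gene_first_attr(ann$features, "ll_id") |>
                rename(ll_id = "value"), by = "gene_id") |>
    left_join(gene_first_attr(ann$features, "gene_description") |>
                rename(name = "value"), by = "gene_id")

  xw <- function(key) {
    cw <- crosswalks[[key]]
    if (is.null(cw)) {
      return(tibble(gene_id = character(), external_id = character()))
    }
    stopifnot(all(c("gene_id", "external_id") %in% names(cw)))
    dup <- cw |> count(.data$gene_id) |> filter(.data$n > 1L)
    if (nrow(dup) > 0) {
      warn(paste0("crosswalk '", key, "' has ", nrow(dup),
                  " gene ID(s) with multiple targets; keeping first by sort"))
    }
    cw |>
      arrange(.data$gene_id, .data$external_id) |>
      distinct(.data$gene_id, .keep_all = TRUE) |>
      select("gene_id", "external_id")
  }
  ens <- xw("ensembl") |> rename(ensembl_gene_id = "external_id")
  ncbi <- xw("ncbi") |> rename(ncbi_id = "external_id")
  zfin <- xw("zfin") |> rename(zfin_id = "external_id")

  note_from <- function(report) {
    if (is.null(report)) {
      return(tibble(gene_id = character(), note = character()))
    }
    report$gene_pairs |>
      transmute(
        gene_id = .data$query_gene,
        note = ifelse(.data$confidence == "transcript_match",
                      "full_transcript_match", "gene_coordinate_overlap")
      ) |>
      distinct(.data$gene_id, .keep_all = TRUE)
  }
  notes <- bind_rows(note_from(report_ens), note_from(report_refseq)) |>
    mutate(rank = ifelse(.data$note == "full_transcript_match", 1L, 2L)) |>
    group_by(.data$gene_id) |>
    arrange(.data$rank, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("gene_id", "note")

  added_note <- gene_first_attr(ann$features, "match_note") |>
    rename(added = "value")

  genes |>
    left_join(ens, by = "gene_id") |>
    left_join(ncbi, by = "gene_id") |>
    left_join(zfin, by = "gene_id") |>
    left_join(notes, by = "gene_id") |>
    left_join(added_note, by = "gene_id") |>
    mutate(
      match_note = dplyr::case_when(
        !is.na(.data$added) ~ .data$added,
        !is.na(.data$note) ~ .data$note,
        startsWith(.data$gene_id, "XLOC") ~ "novel_xloc",
        TRUE ~ "unmatched"
      )
    ) |>
    arrange(as.integer(str_remove(.data$ll_id, "^LL"))) |>
    select("ll_id", "gene_id", "ensembl_gene_id", "ncbi_id", "zfin_id",
           "symbol", "name", "match_note")
}
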