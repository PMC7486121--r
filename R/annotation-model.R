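# Feature kinds recognized in GTF column 3. Unrecognized values are kept
# verbatim in `feature` and mapped to kind "other" so they round-trip.
.kind_map <- c(
  exon             = "exon",
  cds              = "CDS",
  stop_codon       = "stop_codon",
  start_codon      = "start_codon",
  five_prime_utr   = "five_prime_utr",
  "5utr"           = "five_prime_utr",
  utr5             = "five_prime_utr",
  three_prime_utr  = "three_prime_utr",
  "3utr"           = "three_prime_utr",
  utr3             = "three_prime_utr",
  gene             = "gene",
  transcript       = "transcript",
  mrna             = "transcript"
)

canonical_kind <- function(feature) {
  kind <- unname(.kind_map[tolower(feature)])
  dplyr::coalesce(kind, "other")
}

.feature_cols <- c(
  "chrom", "source", "feature", "kind", "start", "end",
  "score", "strand", "frame", "gene_id", "transcript_id", "attr_rest"
)

#' Construct a genome annotation from a feature table
#'
#' A `genome_annotation` is a label plus a tibble of GTF feature rows with
#' 1-based, fully closed coordinates (length = end - start + 1). The gene /
#' transcript hierarchy is implicit in the `gene_id` and `transcript_id`
#' columns; no explicit gene or transcript lines are required.
#'
#' @param features Tibble with columns `chrom`, `source`, `feature`, `start`,
#'   `end`, `score`, `strand`, `frame`, `gene_id`, `transcript_id`,
#'   `attr_rest`. A `kind` column (canonicalized feature type) is derived if
#'   absent. `transcript_id` may be `NA` only on gene-level lines.
#' @param label Short display label for the annotation (e.g. `"Ens95"`).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(features, label = "annotation") {
  stopifnot(is.data.frame(features))
  features <- as_tibble(features)
  if (nrow(features) == 0) {
    features <- tibble(
      chrom = character(), source = character(), feature = character(),
      kind = character(), start = integer(), end = integer(),
      score = character(), strand = character(), frame = character(),
      gene_id = character(), transcript_id = character(),
      attr_rest = character()
    )
  }
  if (!"kind" %in% names(features)) {
    features$kind <- canonical_kind(features$feature)
  }
  missing_cols <- setdiff(.feature_cols, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  features <- features[, .feature_cols]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- which(features$start > features$end)
  if (length(bad) > 0) {
    abort(paste0("start > end for ", length(bad), " feature(s), e.g. ",
                 features$gene_id[bad[1]]))
  }
  structure(
    list(label = label, features = features),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  g <- ann_genes(x)
  tx <- ann_transcripts(x)
  cat(sprintf(
    "<genome_annotation> %s: %d genes, %d transcripts, %d exon rows on %d sequence(s)\n",
    x$label, nrow(g), nrow(tx), sum(x$features$kind == "exon"),
    dplyr::n_distinct(x$features$chrom)
  ))
  invisible(x)
}

#' @rdname genome_annotation
#' @param x An object.
#' @export
is_genome_annotation <- function(x) inherits(x, "genome_annotation")

#' Feature, gene and transcript tables of an annotation
#'
#' `ann_features()` returns the raw feature rows. `ann_transcripts()` returns
#' one row per transcript with its span and exon count. `ann_genes()` returns
#' one row per gene with span, symbol (`gene_name` attribute), biotype
#' (`gene_biotype`/`gene_type`/`biotype` attribute), transcript count, and a
#' `split` flag set when a gene's features sit on more than one chromosome
#' (such genes are retained, not rejected; the curation step consumes the
#' flag).
#'
#' @param ann A [genome_annotation].
#' @return A tibble.
#' @export
ann_features <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  ann$features
}

#' @rdname ann_features
#' @export
ann_transcripts <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  if (nrow(ann$features) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), n_exons = integer()
    ))
  }
  ann$features |>
    filter(!is.na(.data$transcript_id), .data$kind == "exon") |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_exons = dplyr::n(),
      .groups = "drop"
    )
}

#' @rdname ann_features
#' @export
ann_genes <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  feats <- ann$features
  if (nrow(feats) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), symbol = character(),
      biotype = character(), n_transcripts = integer(), split = logical()
    ))
  }
  base <- feats |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = dplyr::n_distinct(.data$transcript_id, na.rm = TRUE),
      split = dplyr::n_distinct(.data$chrom) > 1L,
      .groups = "drop"
    )
  sym <- gene_first_attr(feats, "gene_name") |> rename(symbol = "value")
  bio <- feats |>
    mutate(value = dplyr::coalesce(
      gtf_attr(.data$attr_rest, "gene_biotype"),
      gtf_attr(.data$attr_rest, "gene_type"),
      gtf_attr(.data$attr_rest, "biotype")
    )) |>
    filter(!is.na(.data$value)) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", biotype = "value")
  base |>
    left_join(sym, by = "gene_id") |>
    left_join(bio, by = "gene_id") |>
    select("gene_id", "chrom", "strand", "start", "end", "symbol",
           "biotype", "n_transcripts", "split")
}

# First non-NA value of a GTF attribute per gene, vectorized over all rows.
gene_first_attr <- function(feats, key) {
  feats |>
    mutate(value = gtf_attr(.data$attr_rest, key)) |>
    filter(!is.na(.data$value)) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "value")
}

# First non-NA value of a GTF attribute across a gene's rows (grouped use).
first_attr <- function(attr_rest, key) {
  v <- gtf_attr(attr_rest, key)
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_character_ else v[1]
}

#' Extract a GTF attribute value
#'
#' Pulls `key "value";` out of stored attribute strings. Vectorized over the
#' attribute column; returns `NA` where the key is absent.
#'
#' @param attrs Character vector of GTF attribute strings.
#' @param key Attribute key, e.g. `"gene_name"`.
#' @return Character vector of values.
#' @export
gtf_attr <- function(attrs, key) {
  m <- str_match(attrs, paste0("(?:^|; ?)", key, ' "([^"]*)"'))
  m[, 2]
}

# Set (add or replace) an attribute in attribute-rest strings.
set_gtf_attr <- function(attrs, key, value) {
  attrs <- ifelse(is.na(attrs), "", attrs)
  pat <- paste0("(^|; ?)", key, ' "[^"]*";?')
  has <- str_detect(attrs, pat)
  repl <- paste0("\\1", key, ' "', value, '";')
  out <- attrs
  out[has] <- str_replace(attrs[has], pat, repl[has])
  add <- !has & !is.na(value)
  out[add] <- str_trim(paste0(attrs[add], " ", key, ' "', value[add], '";'))
  out
}

#' Exon table of an annotation
#'
#' Exon rows with gene and transcript IDs, sorted in genomic order within each
#' transcript. Internal substrate for interval arithmetic.
#'
#' @param ann A [genome_annotation].
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id`.
#' @export
ann_exons <- function(ann) {
  stopifnot(is_genome_annotation(ann))
  ann$features |>
    filter(.data$kind == "exon") |>
    select("chrom", "start", "end", "strand", "gene_id", "transcript_id") |>
    arrange(.data$transcript_id, .data$start)
}

# GRanges view of an exon-like tibble (chrom/start/end/strand + id columns).
exons_as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
}

#' Keep or drop genes and transcripts of an annotation
#'
#' `ann_keep_genes()` subsets an annotation to the given gene IDs;
#' `ann_drop_genes()` removes them. Both preserve feature rows verbatim.
#'
#' @param ann A [genome_annotation].
#' @param gene_ids Character vector of gene IDs.
#' @return A [genome_annotation].
#' @export
ann_keep_genes <- function(ann, gene_ids) {
  genome_annotation(
    ann$features |> filter(.data$gene_id %in% gene_ids),
    label = ann$label
  )
}

#' @rdname ann_keep_genes
#' @export
ann_drop_genes <- function(ann, gene_ids) {
  genome_annotation(
    ann$features |> filter(!(.data$gene_id %in% gene_ids)),
    label = ann$label
  )
}
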