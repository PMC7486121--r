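#' Read a GTF file into a genome annotation
#'
#' Parses a 9-column tab-delimited GTF. The gene/transcript hierarchy is
#' reconstructed from the `gene_id` and `transcript_id` attributes, so files
#' without explicit gene or transcript lines (many RefSeq/UCSC exports) parse
#' fine. Chromosome names can be normalized through a two-column alias table
#' (as when reconciling Ensembl and UCSC naming), and alternate-locus contigs
#' can be dropped.
#'
#' @param path Path to a GTF file.
#' @param label Annotation label; defaults to the file name.
#' @param alias_table Optional chromosome alias map: a two-column data frame
#'   (old name, new name) or a named character vector `c(old = new)`.
#' @param drop_alt Drop features on chromosomes matching `alt_pattern`.
#' @param alt_pattern Regular expression identifying alternate-locus /
#'   unplaced contig names.
#' @param strict If `TRUE`, a chromosome name with no alias-table entry is an
#'   error (only meaningful with `alias_table`).
#' @return A [genome_annotation].
#' @export
read_gtf <- function(path, label = basename(path), alias_table = NULL,
                     drop_alt = FALSE, alt_pattern = "_alt|_random",
                     strict = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(genome_annotation(tibble(), label = label))

  parts <- stringr::str_split(lines, stringr::fixed("\t"))
  ncols <- lengths(parts)
  bad <- which(ncols != 9L)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed GTF line %d in %s: expected 9 tab-separated columns, found %d",
      line_no[bad[1]], path, ncols[bad[1]]
    ))
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  attrs <- m[, 9]
  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  feature <- m[, 3]
  kind <- canonical_kind(feature)

  no_gid <- which(is.na(gene_id))
  if (length(no_gid) > 0) {
    abort(sprintf("GTF line %d in %s lacks a gene_id attribute",
                  line_no[no_gid[1]], path))
  }
  need_tx <- kind != "gene"
  no_tx <- which(need_tx & is.na(transcript_id))
  if (length(no_tx) > 0) {
    abort(sprintf(
      "GTF line %d in %s (%s feature) lacks a transcript_id attribute",
      line_no[no_tx[1]], path, feature[no_tx[1]]
    ))
  }

  # Remainder of the attribute string with gene_id/transcript_id stripped;
  # preserved verbatim so unknown attributes survive a round trip.
  attr_rest <- attrs |>
    str_remove('(^|;)\\s*gene_id "[^"]*";?') |>
    str_remove('(^|;)\\s*transcript_id "[^"]*";?') |>
    str_trim()

  feats <- tibble(
    chrom = m[, 1], source = m[, 2], feature = feature, kind = kind,
    start = suppressWarnings(as.integer(m[, 4])),
    end = suppressWarnings(as.integer(m[, 5])),
    score = m[, 6], strand = m[, 7], frame = m[, 8],
    gene_id = gene_id, transcript_id = transcript_id, attr_rest = attr_rest
  )
  bad_coord <- which(is.na(feats$start) | is.na(feats$end))
  if (length(bad_coord) > 0) {
    abort(sprintf("malformed GTF line %d in %s: non-integer coordinates",
                  line_no[bad_coord[1]], path))
  }

  if (!is.null(alias_table)) {
    map <- as_alias_map(alias_table)
    aliased <- feats$chrom %in% names(map)
    if (strict && any(!aliased)) {
      unknown <- unique(feats$chrom[!aliased])
      abort(paste0("chromosome name(s) with no alias: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    feats$chrom[aliased] <- unname(map[feats$chrom[aliased]])
  }
  if (drop_alt) {
    feats <- feats |> filter(!str_detect(.data$chrom, alt_pattern))
  }
  genome_annotation(feats, label = label)
}

as_alias_map <- function(alias_table) {
  if (is.data.frame(alias_table)) {
    stats::setNames(as.character(alias_table[[2]]),
                    as.character(alias_table[[1]]))
  } else if (is.character(alias_table) && !is.null(names(alias_table))) {
    alias_table
  } else {
    abort("alias_table must be a two-column data frame or named character vector")
  }
}

#' Read a chromosome alias table
#'
#' Two-column TSV (no header): old name, new name.
#'
#' @param path Path to a TSV file.
#' @return Named character vector suitable for `read_gtf(alias_table = )`.
#' @export
read_alias_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("old", "new"),
                        col_types = "cc", progress = FALSE)
  stats::setNames(df$new, df$old)
}

#' Write a genome annotation to a GTF file
#'
#' Features are emitted sorted by chromosome, start, gene, transcript and
#' feature kind, with attributes ordered `gene_id`, `transcript_id`, then all
#' others as stored. Output is byte-stable across runs, and
#' `read_gtf(write_gtf(ann))` reproduces the annotation feature-for-feature.
#'
#' @param ann A [genome_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(is_genome_annotation(ann))
  if (nrow(ann$features) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  kind_rank <- c(gene = 0L, transcript = 1L, exon = 2L, CDS = 3L,
                 start_codon = 4L, stop_codon = 5L,
                 five_prime_utr = 6L, three_prime_utr = 7L, other = 8L)
  feats <- ann$features |>
    mutate(.krank = unname(kind_rank[.data$kind])) |>
    arrange(.data$chrom, .data$start, .data$gene_id,
            !is.na(.data$transcript_id), .data$transcript_id,
            .data$.krank, .data$end)
  attr9 <- paste0('gene_id "', feats$gene_id, '";')
  has_tx <- !is.na(feats$transcript_id)
  attr9[has_tx] <- paste0(attr9[has_tx],
                          ' transcript_id "', feats$transcript_id[has_tx], '";')
  has_rest <- !is.na(feats$attr_rest) & nzchar(feats$attr_rest)
  attr9[has_rest] <- paste(attr9[has_rest], feats$attr_rest[has_rest])
  out <- paste(feats$chrom, feats$source, feats$feature, feats$start,
               feats$end, feats$score, feats$strand, feats$frame, attr9,
               sep = "\t")
  readr::write_lines(out, path)
  invisible(path)
}
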