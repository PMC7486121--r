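# Hand-built annotations for unit tests. All coordinates are 1-based closed.

# One transcript's feature rows. exons/cds/utr3 are lists of c(start, end);
# stop is a single c(start, end) or NULL.
tx_rows <- function(gene, tx, chrom = "chr1", strand = "+", exons,
                    cds = list(), stop = NULL, utr3 = list(),
                    symbol = NULL, biotype = NULL) {
  attrs <- paste0(
    if (!is.null(symbol)) paste0('gene_name "', symbol, '"; ') else "",
    if (!is.null(biotype)) paste0('gene_biotype "', biotype, '"; ') else ""
  )
  attrs <- trimws(attrs)
  row <- function(kind, iv) {
    tibble::tibble(
      chrom = chrom, source = "test", feature = kind, kind = kind,
      start = iv[1], end = iv[2], score = ".", strand = strand, frame = ".",
      gene_id = gene, transcript_id = tx, attr_rest = attrs
    )
  }
  dplyr::bind_rows(
    purrr::map(exons, ~ row("exon", .x)),
    purrr::map(cds, ~ row("CDS", .x)),
    if (!is.null(stop)) row("stop_codon", stop),
    purrr::map(utr3, ~ row("three_prime_utr", .x))
  )
}

ann_of <- function(..., label = "test") {
  genome_annotation(dplyr::bind_rows(...), label = label)
}

# A 2-exon coding gene with a 3' UTR in its last exon, at an offset.
std_gene <- function(gene, tx, offset = 0, chrom = "chr1", strand = "+",
                     symbol = NULL, biotype = "protein_coding") {
  if (strand == "+") {
    tx_rows(gene, tx, chrom, strand,
            exons = list(c(100, 300) + offset, c(500, 1000) + offset),
            cds = list(c(100, 300) + offset, c(500, 700) + offset),
            stop = c(701, 703) + offset,
            utr3 = list(c(704, 1000) + offset),
            symbol = symbol, biotype = biotype)
  } else {
    tx_rows(gene, tx, chrom, strand,
            exons = list(c(100, 600) + offset, c(800, 1000) + offset),
            cds = list(c(400, 600) + offset, c(800, 1000) + offset),
            stop = c(397, 399) + offset,
            utr3 = list(c(100, 396) + offset),
            symbol = symbol, biotype = biotype)
  }
}

# Tiny fixture-generator config that keeps unit tests fast.
small_cfg <- function(n_genes = 80, seed = 1, ...) {
  fixture_config(n_genes = n_genes, seed = seed, ...)
}

sorted_feature_frame <- function(ann) {
  d <- ann_features(ann)[, c("chrom", "start", "end", "strand", "feature",
                             "gene_id", "transcript_id", "attr_rest")]
  d <- dplyr::arrange(d, .data$chrom, .data$start, .data$end, .data$feature,
                      .data$gene_id, .data$transcript_id)
  d <- as.data.frame(d)
  rownames(d) <- NULL
  d
}
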