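test_that("a minimal GTF parses into the expected hierarchy", {
  lines <- c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t300\t350\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tstop_codon\t351\t353\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tthree_prime_utr\t354\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  )
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(lines, f)
  ann <- read_gtf(f, label = "mini")
  expect_equal(nrow(ann_genes(ann)), 1)
  expect_equal(nrow(ann_transcripts(ann)), 1)
  expect_equal(sum(ann_features(ann)$kind == "exon"), 2)
  expect_equal(utr3_length(ann, "t1"), 47)
})

test_that("chromosome aliasing is a pure relabeling and alt contigs drop", {
  ann <- ann_of(
    std_gene("g1", "t1", chrom = "1"),
    std_gene("g2", "t2", chrom = "1_random", offset = 2000)
  )
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  renamed <- read_gtf(f, alias_table = c("1" = "chr1"))
  expect_equal(nrow(ann_features(renamed)), nrow(ann_features(ann)))
  expect_true("chr1" %in% renamed$features$chrom)
  expect_false("1" %in% renamed$features$chrom)

  dropped <- read_gtf(f, drop_alt = TRUE)
  expect_equal(sort(unique(dropped$features$gene_id)), "g1")

  expect_error(read_gtf(f, alias_table = c("1" = "chr1"), strict = TRUE),
               "no alias")
})

test_that("malformed GTF lines fail with a line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line"
  ), f)
  expect_error(read_gtf(f), "line 2")

  writeLines(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1";', f)
  expect_error(read_gtf(f), "transcript_id")

  # gene-level lines need no transcript_id
  writeLines(c(
    'chr1\tsrc\tgene\t100\t200\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), f)
  expect_silent(ann <- read_gtf(f))
  expect_equal(nrow(ann_genes(ann)), 1)
})

test_that("write/read round trip preserves features and is byte-stable", {
  sim <- simulate_annotations(small_cfg(n_genes = 60, seed = 2))
  for (ann in list(sim$annA, sim$annB, sim$merged)) {
    f <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(ann, f)
    back <- read_gtf(f, label = ann$label)
    expect_identical(sorted_feature_frame(ann), sorted_feature_frame(back))
    f2 <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }

  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genome_annotation(tibble::tibble()), f)
  expect_equal(nrow(ann_genes(read_gtf(f))), 0)
})

test_that("parser agrees with rtracklayer on a generated annotation", {
  skip_if_not_installed("rtracklayer")
  sim <- simulate_annotations(small_cfg(n_genes = 40, seed = 9))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annA, f)
  gr <- rtracklayer::import(f, format = "gtf")
  ours <- ann_features(sim$annA)
  expect_equal(length(gr), nrow(ours))
  expect_equal(sum(gr$type == "exon"), sum(ours$kind == "exon"))
  expect_equal(length(unique(gr$gene_id)), nrow(ann_genes(sim$annA)))
  expect_equal(sort(unique(as.character(GenomicRanges::seqnames(gr)))),
               sort(unique(ours$chrom)))
  # spot-check coordinates of one transcript against the independent parser
  tx1 <- ours$transcript_id[ours$kind == "exon"][1]
  ours_ex <- ours[ours$kind == "exon" & ours$transcript_id == tx1, ]
  gr_ex <- gr[gr$type == "exon" & !is.na(gr$transcript_id) &
                gr$transcript_id == tx1]
  expect_equal(sort(GenomicRanges::start(gr_ex)), sort(ours_ex$start))
  expect_equal(sort(GenomicRanges::end(gr_ex)), sort(ours_ex$end))
})

test_that("3' UTR length sums closed intervals and ignores order and strand", {
  ann <- ann_of(
    tx_rows("g1", "t1", exons = list(c(1001, 1200)),
            utr3 = list(c(1001, 1200))),
    tx_rows("g2", "t2", exons = list(c(2000, 2200), c(2500, 2600)),
            utr3 = list(c(2051, 2200), c(2500, 2549))),
    tx_rows("g3", "t3", exons = list(c(3000, 3400)),
            cds = list(c(3000, 3400)))
  )
  lens <- utr3_lengths(ann)
  expect_equal(lens$utr3_len[lens$transcript_id == "t1"], 200)
  expect_equal(lens$utr3_len[lens$transcript_id == "t2"], 200)
  expect_equal(lens$utr3_len[lens$transcript_id == "t3"], 0)

  # reordering segment rows must not matter
  shuffled <- genome_annotation(ann$features[rev(seq_len(nrow(ann$features))), ])
  expect_equal(
    dplyr::arrange(utr3_lengths(shuffled), transcript_id)$utr3_len,
    dplyr::arrange(lens, transcript_id)$utr3_len
  )

  # minus-strand segments: computation uses segments, not orientation
  mins <- ann_of(tx_rows("g4", "t4", strand = "-",
                         exons = list(c(100, 400)), utr3 = list(c(100, 299))))
  expect_equal(utr3_length(mins, "t4"), 200)
})

test_that("3' UTRs derive from CDS and stop codon on both strands", {
  plus <- ann_of(tx_rows("g1", "t1", exons = list(c(1, 300)),
                         cds = list(c(1, 240)), stop = c(241, 243)))
  out <- derive_utr3_from_cds(plus)
  expect_equal(utr3_length(out$annotation, "t1"), 57)
  seg <- out$annotation$features |>
    dplyr::filter(kind == "three_prime_utr")
  expect_equal(c(seg$start, seg$end), c(244, 300))

  minus <- ann_of(tx_rows("g2", "t2", strand = "-", exons = list(c(1, 300)),
                          cds = list(c(61, 300)), stop = c(58, 60)))
  out2 <- derive_utr3_from_cds(minus)
  seg2 <- out2$annotation$features |>
    dplyr::filter(kind == "three_prime_utr")
  expect_equal(c(seg2$start, seg2$end), c(1, 57))

  # idempotent when a UTR is already annotated
  out3 <- derive_utr3_from_cds(out$annotation)
  expect_identical(out3$annotation$features, out$annotation$features)

  # no stop codon: flagged, unchanged
  nostop <- ann_of(tx_rows("g3", "t3", exons = list(c(1, 300)),
                           cds = list(c(1, 240))))
  out4 <- derive_utr3_from_cds(nostop)
  expect_equal(out4$underivable$transcript_id, "t3")
  expect_identical(out4$annotation$features, nostop$features)
})
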