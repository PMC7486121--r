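test_that("fusion transcripts are flagged by the same-strand two-gene rule", {
  refA <- ann_of(std_gene("ga", "ta", offset = 0),
                 std_gene("gb", "tb", offset = 3000), label = "refA")
  # spans exons of both genes, same strand, 300 bp overlap each
  fusion <- ann_of(
    tx_rows("gm", "tfus", exons = list(c(100, 300), c(3100, 3300))),
    std_gene("gm2", "tm2", offset = 6000),
    label = "merged"
  )
  flags <- detect_fusion_transcripts(fusion, list(refA))
  expect_equal(flags$transcript_id, "tfus")
  expect_equal(flags$n_genes, 2)

  # opposite-strand overlap does not count
  refB <- ann_of(std_gene("ga", "ta", offset = 0),
                 std_gene("gb", "tb", offset = 3000, strand = "-"),
                 label = "refB")
  expect_equal(nrow(detect_fusion_transcripts(fusion, list(refB))), 0)

  # overlaps below the threshold do not count
  expect_equal(
    nrow(detect_fusion_transcripts(fusion, list(refA),
                                   min_overlap_bp = 500)), 0)
})

test_that("fixture fusions are recovered exactly and removal is idempotent", {
  sim <- simulate_annotations(small_cfg(n_genes = 120, seed = 14))
  flags <- detect_fusion_transcripts(sim$merged, list(sim$annA, sim$annB))
  expect_equal(sort(flags$transcript_id), sim$predictions$fusion_transcripts)
  pruned <- remove_transcripts(sim$merged, flags$transcript_id)$annotation
  again <- detect_fusion_transcripts(pruned, list(sim$annA, sim$annB))
  expect_equal(nrow(again), 0)
})

test_that("removing transcripts drops emptied genes and rejects unknown IDs", {
  ann <- ann_of(
    std_gene("g1", "t1"),
    std_gene("g2", "t2a", offset = 3000),
    std_gene("g2", "t2b", offset = 3000)
  )
  res <- remove_transcripts(ann, "t1")
  expect_equal(res$removed_genes, "g1")
  expect_false("g1" %in% ann_genes(res$annotation)$gene_id)

  res2 <- remove_transcripts(ann, "t2a")
  expect_length(res2$removed_genes, 0)
  expect_equal(ann_genes(res2$annotation)$n_transcripts[
    ann_genes(res2$annotation)$gene_id == "g2"], 1)

  expect_error(remove_transcripts(ann, "nope"), "unknown transcript")
})

test_that("small-RNA removal spares miRNAs and tolerates unlabeled input", {
  rrna <- purrr::map(1:20, function(i) {
    tx_rows(paste0("r", i), paste0("rt", i),
            exons = list(c(100, 200) + i * 1000), biotype = "rRNA")
  })
  mirna <- purrr::map(1:5, function(i) {
    tx_rows(paste0("m", i), paste0("mt", i),
            exons = list(c(100, 180) + (i + 30) * 1000), biotype = "miRNA")
  })
  ann <- ann_of(rrna, mirna)
  res <- remove_small_rna(ann)
  expect_length(res$removed_genes, 20)
  expect_equal(nrow(ann_genes(res$annotation)), 5)
  # miRNA survives even if someone puts it in the removal set
  res2 <- remove_small_rna(ann, biotypes = c("rRNA", "miRNA"))
  expect_equal(nrow(ann_genes(res2$annotation)), 5)

  plain <- ann_of(std_gene("g1", "t1", biotype = NULL))
  expect_warning(res3 <- remove_small_rna(plain), "no biotype")
  expect_equal(nrow(ann_genes(res3$annotation)), 1)

  expect_identical(remove_small_rna(ann, biotypes = character(0))$annotation,
                   ann)
})

test_that("nomenclature follows source priority and records conflicts", {
  ens <- ann_of(std_gene("e1", "et1", symbol = "alpha"), label = "ens")
  refseq <- ann_of(std_gene("r1", "rt1", symbol = "alpha_rs"),
                   std_gene("r2", "rt2", offset = 3000, symbol = "beta"),
                   label = "refseq")
  merged <- ann_of(std_gene("m1", "mt1"),
                   std_gene("m2", "mt2", offset = 3000),
                   std_gene("m3", "mt3", offset = 9000),
                   label = "merged")
  rep_e <- match_annotations(merged, ens)
  rep_r <- match_annotations(merged, refseq)
  nom <- assign_nomenclature(merged, ens, refseq, rep_e, rep_r)
  asg <- nom$assignments
  expect_equal(asg$symbol[asg$gene_id == "m1"], "alpha")      # ens wins
  expect_equal(asg$source[asg$gene_id == "m1"], "ensembl")
  expect_equal(asg$symbol[asg$gene_id == "m2"], "beta")       # refseq fallback
  expect_match(asg$symbol[asg$gene_id == "m3"], "^XLOC_")     # novel
  # symbols are written into the annotation's attributes
  g <- ann_genes(nom$annotation)
  expect_equal(g$symbol[g$gene_id == "m1"], "alpha")
})

test_that("a merged gene spanning two differently named genes is a conflict", {
  ens <- ann_of(std_gene("e1", "et1", symbol = "cpn1"),
                std_gene("e2", "et2", offset = 3000, symbol = "gstz1"),
                label = "ens")
  refseq <- genome_annotation(tibble::tibble(), label = "refseq")
  merged <- ann_of(
    tx_rows("m1", "mt1", exons = list(c(100, 300), c(3100, 3300))),
    label = "merged"
  )
  nom <- assign_nomenclature(merged, ens, refseq,
                             match_annotations(merged, ens),
                             match_annotations(merged, refseq))
  confl <- nom$conflicts
  expect_true("multiple_reference_symbols" %in% confl$type)
  expect_match(confl$symbol[confl$type == "multiple_reference_symbols"],
               "cpn1,gstz1")
})

test_that("add-back copies missing genes verbatim and respects collisions", {
  sim <- simulate_annotations(small_cfg(n_genes = 120, seed = 15))
  res <- curate_annotation(sim$merged, sim$annA, sim$annB,
                           evidence = sim$evidence, lincrnas = sim$lincrnas)
  p <- sim$predictions
  added_A <- res$added$gene_id[res$added$ref == "ens"]
  expect_equal(sort(added_A), p$merged_missing_vs_A)
  # the same loci arriving from the second reference are skipped, while the
  # B-only split gene is genuinely added from B
  expect_setequal(res$skipped$gene_id,
                  setdiff(p$merged_missing_vs_B, names(p$split_kept_chrom)))
  expect_true(all(names(p$split_kept_chrom) %in% res$added$gene_id))

  # empty missing list leaves the annotation unchanged
  ab <- add_back_missing(sim$merged, list(ens = character(0)),
                         refs = list(ens = sim$annA))
  expect_identical(ab$annotation$features, sim$merged$features)
})

test_that("split genes contribute only their larger piece with the 3' UTR", {
  sim <- simulate_annotations(small_cfg(n_genes = 120, seed = 15))
  res <- curate_annotation(sim$merged, sim$annA, sim$annB,
                           evidence = sim$evidence, lincrnas = sim$lincrnas)
  kept <- sim$predictions$split_kept_chrom
  for (gid in names(kept)) {
    rows <- res$annotation$features |> dplyr::filter(gene_id == gid)
    expect_gt(nrow(rows), 0)
    expect_equal(unique(rows$chrom), unname(kept[gid]))
    expect_true(any(rows$kind == "three_prime_utr"))
  }
})

test_that("LL IDs are positional, deterministic and unique", {
  ann <- ann_of(
    std_gene("zzz", "tz", chrom = "chr1", offset = 0),
    std_gene("aaa", "ta", chrom = "chr1", offset = 5000),
    std_gene("mmm", "tm", chrom = "chr2", offset = 0)
  )
  ll <- assign_ll_ids(ann)
  expect_equal(ll$table$ll_id, c("LL1", "LL2", "LL3"))
  expect_equal(ll$table$gene_id, c("zzz", "aaa", "mmm"))
  # deterministic re-run
  expect_identical(assign_ll_ids(ann)$table, ll$table)
  # ties at identical start resolved by gene ID
  tie <- ann_of(
    std_gene("gB", "tB", offset = 0),
    std_gene("gA", "tA", offset = 0, strand = "-")
  )
  expect_equal(assign_ll_ids(tie)$table$gene_id, c("gA", "gB"))
  # ll_id attribute survives a GTF round trip
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ll$annotation, f)
  back <- read_gtf(f)
  expect_equal(sort(unique(gtf_attr(back$features$attr_rest, "ll_id"))),
               sort(ll$table$ll_id))
})

test_that("gene info records carry external IDs, notes and XLOC flags", {
  ens <- ann_of(std_gene("e1", "et1", symbol = "alpha"), label = "ens")
  merged <- ann_of(std_gene("m1", "mt1", symbol = "alpha"),
                   tx_rows("XLOC_9", "xt1",
                           exons = list(c(9000, 9400), c(9600, 9900))),
                   label = "merged")
  ll <- assign_ll_ids(merged)
  rep_e <- match_annotations(merged, ens)
  info <- build_gene_info(
    ll$annotation,
    crosswalks = list(
      ensembl = tibble::tibble(gene_id = "m1", external_id = "ENSDARG1"),
      zfin = tibble::tibble(gene_id = "m1", external_id = "ZDB-GENE-1")
    ),
    report_ens = rep_e
  )
  m1 <- info[info$gene_id == "m1", ]
  expect_equal(m1$ensembl_gene_id, "ENSDARG1")
  expect_equal(m1$zfin_id, "ZDB-GENE-1")
  expect_equal(m1$match_note, "full_transcript_match")
  x <- info[info$gene_id == "XLOC_9", ]
  expect_equal(x$match_note, "novel_xloc")
  expect_true(is.na(x$ensembl_gene_id))
  expect_false(anyDuplicated(info$ll_id) > 0)

  # empty crosswalks still yield complete records
  info2 <- build_gene_info(ll$annotation)
  expect_equal(nrow(info2), 2)
  expect_true(all(is.na(info2$ncbi_id)))
})

test_that("curation conserves gene counts end to end", {
  sim <- simulate_annotations(small_cfg(n_genes = 120, seed = 16))
  res <- curate_annotation(sim$merged, sim$annA, sim$annB,
                           evidence = sim$evidence, lincrnas = sim$lincrnas)
  s <- res$summary
  expect_equal(
    s$n_merged - s$n_genes_lost_with_fusions - s$n_small_rna_removed -
      s$n_xloc_removed + s$n_added_back,
    s$n_curated
  )
  expect_equal(res$small_rna_removed, sim$predictions$small_rna_removed)
  # after fusion removal only the planted duplicate-symbol conflicts remain
  expect_equal(nrow(res$conflicts),
               sim$predictions$n_symbol_conflicts_after_curation)
  expect_true(all(res$conflicts$type == "symbol_on_multiple_loci"))
  # every curated gene has exactly one info record with a unique LL ID
  expect_equal(nrow(res$gene_info), s$n_curated)
  expect_false(anyDuplicated(res$gene_info$ll_id) > 0)
})
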