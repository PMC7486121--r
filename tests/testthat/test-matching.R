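test_that("intron chains list junctions in genomic order", {
  ann <- ann_of(
    tx_rows("g1", "t1", exons = list(c(1, 100), c(201, 300))),
    tx_rows("g2", "t2", exons = list(c(1000, 1400))),
    tx_rows("g3", "t3", exons = list(c(2000, 2100), c(2200, 2300),
                                     c(2400, 2500), c(2600, 2700),
                                     c(2800, 2900)))
  )
  ch <- intron_chains(ann)
  j1 <- ch[ch$transcript_id == "t1", ]
  expect_equal(j1$donor, 100)
  expect_equal(j1$acceptor, 201)
  expect_false("t2" %in% ch$transcript_id)
  j3 <- ch[ch$transcript_id == "t3", ]
  expect_equal(nrow(j3), 4)
  expect_true(all(diff(j3$donor) > 0) && all(j3$donor < j3$acceptor))
})

test_that("pairwise class codes follow the structural rules", {
  r <- ann_of(tx_rows("gr", "tr", exons = list(c(100, 300), c(500, 800),
                                               c(900, 1200))))
  # identical transcript: full match
  q_same <- ann_of(tx_rows("gq", "tq", exons = list(c(100, 300), c(500, 800),
                                                    c(900, 1200))))
  expect_equal(classify_pair(q_same, r, "tq", "tr"), "=")

  # same introns, 3' terminal exon 500 nt longer: still a full match
  q_ext <- ann_of(tx_rows("gq", "tq", exons = list(c(100, 300), c(500, 800),
                                                   c(900, 1700))))
  expect_equal(classify_pair(q_ext, r, "tq", "tr"), "=")

  # contiguous sub-chain: contained
  q_sub <- ann_of(tx_rows("gq", "tq", exons = list(c(550, 800), c(900, 1100))))
  expect_equal(classify_pair(q_sub, r, "tq", "tr"), "c")

  # one shared junction, one novel: junction overlap
  q_j <- ann_of(tx_rows("gq", "tq", exons = list(c(100, 300), c(500, 700),
                                                 c(950, 1200))))
  expect_equal(classify_pair(q_j, r, "tq", "tr"), "j")

  # same-strand exonic overlap without shared junctions
  q_o <- ann_of(tx_rows("gq", "tq", exons = list(c(250, 550))))
  expect_equal(classify_pair(q_o, r, "tq", "tr"), "o")

  # opposite strand only: antisense
  q_x <- ann_of(tx_rows("gq", "tq", strand = "-", exons = list(c(100, 1200))))
  expect_equal(classify_pair(q_x, r, "tq", "tr"), "x")

  # no overlap at all / different chromosome
  q_u <- ann_of(tx_rows("gq", "tq", exons = list(c(5000, 5400))))
  expect_equal(classify_pair(q_u, r, "tq", "tr"), "u")
  q_chr <- ann_of(tx_rows("gq", "tq", chrom = "chr9",
                          exons = list(c(100, 1200))))
  expect_equal(classify_pair(q_chr, r, "tq", "tr"), "u")
})

test_that("single-exon pairs need reciprocal overlap for a full match", {
  r <- ann_of(tx_rows("gr", "tr", exons = list(c(1000, 1999))))  # 1000 nt
  q_good <- ann_of(tx_rows("gq", "tq", exons = list(c(1100, 1999))))  # 900 nt
  expect_equal(classify_pair(q_good, r, "tq", "tr"), "=")  # 900/900 >= 0.8
  # 100 bp overlap of a 501 nt query is neither full nor contained
  q_short <- ann_of(tx_rows("gq", "tq", exons = list(c(1900, 2400))))
  expect_equal(classify_pair(q_short, r, "tq", "tr"), "o")
  # containment implies full overlap of the shorter, so two single-exon
  # transcripts one inside the other satisfy the reciprocal rule
  q_in <- ann_of(tx_rows("gq", "tq", exons = list(c(1200, 1400))))
  expect_equal(classify_pair(q_in, r, "tq", "tr"), "=")
  # against a multi-exon reference the same query is contained
  r_multi <- ann_of(tx_rows("gm", "tm", exons = list(c(1000, 1999),
                                                     c(3000, 3200))))
  expect_equal(classify_pair(q_in, r_multi, "tq", "tm"), "c")
})

test_that("undirected strand features never produce a full match", {
  r <- ann_of(tx_rows("gr", "tr", exons = list(c(100, 999))))
  q_dot <- ann_of(tx_rows("gq", "tq", strand = ".",
                          exons = list(c(100, 999))))
  expect_false(classify_pair(q_dot, r, "tq", "tr") == "=")
  expect_true(classify_pair(q_dot, r, "tq", "tr") %in% c("c", "o"))
})

test_that("self-comparison matches everything and misses nothing", {
  sim <- simulate_annotations(small_cfg(n_genes = 80, seed = 11))
  rep <- match_annotations(sim$annA, sim$annA)
  expect_true(all(rep$transcripts$class == "="))
  expect_length(rep$missing_genes, 0)
})

test_that("confirmed missing genes equal the planted set, with rescue", {
  sim <- simulate_annotations(small_cfg(n_genes = 150, seed = 12))
  repA <- match_annotations(sim$annA, sim$annB)
  expect_equal(repA$missing_genes, sim$predictions$confirmed_missing_from_A)
  repB <- match_annotations(sim$annB, sim$annA)
  expect_equal(repB$missing_genes, sim$predictions$confirmed_missing_from_B)
  # rescued genes were planted absent from A yet are not reported missing
  rescued <- sim$manifest$id[sim$manifest$type == "rescued_A"]
  expect_gt(length(rescued), 0)
  expect_length(intersect(rescued, repA$missing_genes), 0)
})

test_that("a gene with one matched transcript is never missing", {
  ref <- ann_of(
    tx_rows("gr", "tr1", exons = list(c(100, 300), c(500, 800))),
    tx_rows("gr", "tr2", exons = list(c(10000, 10400)))
  )
  query <- ann_of(tx_rows("gq", "tq1", exons = list(c(100, 300), c(500, 800))))
  rep <- match_annotations(query, ref)
  cls <- rep$transcripts
  expect_setequal(cls$class, c("=", "u"))
  expect_length(rep$missing_genes, 0)

  ref2 <- ann_of(tx_rows("gr", "tr2", exons = list(c(10000, 10400))))
  expect_equal(match_annotations(query, ref2)$missing_genes, "gr")
})

test_that("adding query transcripts never increases the missing count", {
  sim <- simulate_annotations(small_cfg(n_genes = 100, seed = 13))
  rep0 <- match_annotations(sim$annA, sim$annB)
  n0 <- length(rep0$missing_genes)
  # restore one missing gene's model (renamed) into the query
  miss <- rep0$missing_genes[1]
  restored <- sim$annB$features |>
    dplyr::filter(gene_id == miss) |>
    dplyr::mutate(gene_id = "RESTORED", transcript_id = "RESTORED_T1")
  annA2 <- genome_annotation(dplyr::bind_rows(sim$annA$features, restored),
                             label = "simA+")
  n1 <- length(match_annotations(annA2, sim$annB)$missing_genes)
  expect_equal(n1, n0 - 1)
})

test_that("full match is symmetric and containment is antisymmetric", {
  a <- ann_of(tx_rows("ga", "ta", exons = list(c(100, 300), c(500, 800),
                                               c(900, 1300))))
  b <- ann_of(tx_rows("gb", "tb", exons = list(c(150, 300), c(500, 800),
                                               c(900, 1100))))
  expect_equal(classify_pair(a, b, "ta", "tb"), "=")
  expect_equal(classify_pair(b, a, "tb", "ta"), "=")
  sub <- ann_of(tx_rows("gs", "ts", exons = list(c(550, 800), c(900, 1000))))
  expect_equal(classify_pair(sub, a, "ts", "ta"), "c")
  expect_false(classify_pair(a, sub, "ta", "ts") == "c")
})

test_that("gene sets intersect through a crosswalk with ambiguity warnings", {
  cw <- tibble::tibble(
    gene_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    shared_id = c("N1", "N2", "N3", "N1", "N2", "N4")
  )
  res <- intersect_gene_sets(c("a1", "a2", "a3"), c("b1", "b2", "b3"), cw)
  expect_equal(res$both, c("N1", "N2"))
  expect_equal(res$a_only, "N3")
  expect_equal(res$b_only, "N4")
  expect_equal(res$n_unmapped_a, 0)

  idf <- intersect_gene_sets(c("a1", "a2"), c("a1", "a2"), cw)
  expect_equal(length(idf$both), 2)
  expect_length(idf$a_only, 0)

  disj <- intersect_gene_sets("a1", "b3", cw)
  expect_equal(c(length(disj$a_only), length(disj$b_only), length(disj$both)),
               c(1, 1, 0))

  # unmapped IDs are excluded and counted
  res2 <- intersect_gene_sets(c("a1", "zz"), "b1", cw)
  expect_equal(res2$n_unmapped_a, 1)

  cw_dup <- dplyr::bind_rows(cw, tibble::tibble(gene_id = "a1",
                                                shared_id = "N9"))
  expect_warning(intersect_gene_sets("a1", "b1", cw_dup), "multiple shared")
})
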