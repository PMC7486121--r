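#' Configuration for the synthetic annotation generator
#'
#' Describes a pair of annotations ("A", Ensembl-like; "B", RefSeq-like) plus
#' a merged assembly, with planted, manifest-recorded discrepancies of every
#' class the toolkit detects. Defaults emulate the discrepancy rates observed
#' between public zebrafish annotations: roughly 18% of coding genes missing
#' any 3' UTR and 6% missing a stop codon on the A side (6% and 1% on the B
#' side), about 30% / 15% of comparable genes with a >50 nt longer 3' UTR in
#' A / B, and roughly 10% / 7% of genes absent from A / B respectively.
#'
#' @param n_genes Number of base protein-coding genes.
#' @param seed Integer seed; identical configs + seed give identical output.
#' @param chrom_sizes Optional named vector of chromosome lengths; by default
#'   chromosomes are sized automatically. Supplying sizes too small for the
#'   requested gene count is an error.
#' @param frac_missing_utr3_A,frac_missing_utr3_B Fraction of the coding genes
#'   present in each annotation whose 3' UTR segments are omitted.
#' @param frac_missing_stop_A,frac_missing_stop_B Fraction with the stop-codon
#'   segment omitted (UTR kept).
#' @param n_utr_longer_A,n_utr_longer_B Genes whose 3' UTR is extended in one
#'   annotation by a delta drawn log-uniformly from `delta_range` (straddling
#'   the 50 nt "longer" threshold from above only).
#' @param n_same_controls Genes given a small delta of at most 50 nt
#'   (same-class controls at the threshold).
#' @param n_utr_longer_C Reference-set genes whose merged model extends the
#'   3' UTR beyond both A and B.
#' @param n_missing_from_A,n_missing_from_B Genes entirely absent from one
#'   annotation.
#' @param n_rescued_A Genes absent from A as gene models but overlapped there
#'   by an unrelated same-strand stub transcript, so the missing-gene
#'   confirmation must rescue them.
#' @param n_missing_from_merged Genes present in both A and B but dropped
#'   from the merged annotation (exercises the add-back step).
#' @param n_anchor_shift_B Genes whose terminal-exon anchor is displaced in B
#'   (excluded from the reference set).
#' @param n_fusion_transcripts Spurious merged transcripts bridging two
#'   adjacent same-strand genes.
#' @param n_duplicate_symbols Pairs of distinct genes sharing one symbol.
#' @param n_small_rna Named counts per small-RNA biotype planted in A, B and
#'   the merged annotation (miRNA entries are never removed by curation).
#' @param n_xloc Named counts of novel loci per class:
#'   `single_exon_no_evidence`, `multi_exon`, `evidence_backed`,
#'   `lincRNA_matched`, `redundant`.
#' @param n_split_genes Genes annotated on two chromosomes in B (absent from
#'   A and merged; the add-back must keep the larger piece).
#' @param delta_range Range (nt) for planted UTR extensions, sampled
#'   log-uniformly; minimum must exceed 50.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 200,
                           seed = 1,
                           chrom_sizes = NULL,
                           frac_missing_utr3_A = 0.18,
                           frac_missing_utr3_B = 0.06,
                           frac_missing_stop_A = 0.06,
                           frac_missing_stop_B = 0.01,
                           n_utr_longer_A = round(0.15 * n_genes),
                           n_utr_longer_B = round(0.08 * n_genes),
                           n_same_controls = round(0.04 * n_genes),
                           n_utr_longer_C = round(0.08 * n_genes),
                           n_missing_from_A = round(0.10 * n_genes),
                           n_missing_from_B = round(0.065 * n_genes),
                           n_rescued_A = round(0.02 * n_genes),
                           n_missing_from_merged = min(3L, n_genes %/% 20L),
                           n_anchor_shift_B = round(0.02 * n_genes),
                           n_fusion_transcripts = min(5L, n_genes %/% 20L),
                           n_duplicate_symbols = min(2L, n_genes %/% 50L),
                           n_small_rna = c(rRNA = 6, snRNA = 3, snoRNA = 3,
                                           sRNA = 2, miscRNA = 2, miRNA = 4),
                           n_xloc = pmin(
                             c(single_exon_no_evidence = 4, multi_exon = 4,
                               evidence_backed = 3, lincRNA_matched = 2,
                               redundant = 3),
                             max(0L, n_genes %/% 25L)),
                           n_split_genes = min(1L, n_genes %/% 40L),
                           delta_range = c(60, 5000)) {
  cfg <- list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    chrom_sizes = chrom_sizes,
    frac_missing_utr3_A = frac_missing_utr3_A,
    frac_missing_utr3_B = frac_missing_utr3_B,
    frac_missing_stop_A = frac_missing_stop_A,
    frac_missing_stop_B = frac_missing_stop_B,
    n_utr_longer_A = as.integer(n_utr_longer_A),
    n_utr_longer_B = as.integer(n_utr_longer_B),
    n_same_controls = as.integer(n_same_controls),
    n_utr_longer_C = as.integer(n_utr_longer_C),
    n_missing_from_A = as.integer(n_missing_from_A),
    n_missing_from_B = as.integer(n_missing_from_B),
    n_rescued_A = as.integer(n_rescued_A),
    n_missing_from_merged = as.integer(n_missing_from_merged),
    n_anchor_shift_B = as.integer(n_anchor_shift_B),
    n_fusion_transcripts = as.integer(n_fusion_transcripts),
    n_duplicate_symbols = as.integer(n_duplicate_symbols),
    n_small_rna = {
      full <- c(rRNA = 0, snRNA = 0, snoRNA = 0, sRNA = 0, miscRNA = 0,
                miRNA = 0)
      bad <- setdiff(names(n_small_rna), names(full))
      if (length(bad) > 0 || is.null(names(n_small_rna))) {
        abort("config error: n_small_rna must be named by known biotypes")
      }
      full[names(n_small_rna)] <- n_small_rna
      full
    },
    n_xloc = {
      full <- c(single_exon_no_evidence = 0, multi_exon = 0,
                evidence_backed = 0, lincRNA_matched = 0, redundant = 0)
      bad <- setdiff(names(n_xloc), names(full))
      if (length(bad) > 0 || is.null(names(n_xloc))) {
        abort("config error: n_xloc must be named by known novel-locus classes")
      }
      full[names(n_xloc)] <- n_xloc
      full
    },
    n_split_genes = as.integer(n_split_genes),
    delta_range = delta_range
  )
  fracs <- unlist(cfg[startsWith(names(cfg), "frac_")])
  if (any(fracs < 0 | fracs > 1)) abort("config error: fractions must be in [0, 1]")
  counts <- unlist(cfg[startsWith(names(cfg), "n_") &
                         names(cfg) != "n_small_rna" & names(cfg) != "n_xloc"])
  if (any(counts < 0)) abort("config error: counts must be non-negative")
  if (cfg$n_genes < 1) abort("config error: n_genes must be positive")
  if (delta_range[1] <= 50) abort("config error: delta_range must start above 50 nt")
  structure(cfg, class = "fixture_config")
}

# log-uniform sample in [lo, hi]
rlogunif <- function(n, lo, hi) {
  round(exp(stats::runif(n, log(lo), log(hi))))
}

#' Generate paired synthetic annotations with a planted-discrepancy manifest
#'
#' Builds three coordinate-compatible annotations - "A" (Ensembl-like), "B"
#' (RefSeq-like) and "merged" (assembly-merge-like, with fusion transcripts
#' and XLOC novel loci) - plus the supporting lincRNA annotation and
#' protein-evidence table for novel-locus triage. Every planted discrepancy
#' is recorded in a manifest, and `$predictions` carries the exact expected
#' output of each analysis module computed from the manifest alone (never by
#' running the modules), so the generator serves as an end-to-end oracle.
#'
#' Gene structures use 1-10 exons of 50-2000 nt with intergenic gaps of at
#' least 500 nt; planted UTR deltas are log-uniform in `delta_range`
#' (straddling the 50 nt threshold from above only, with separate small-delta
#' "same-class" controls).
#'
#' @param config A [fixture_config].
#' @return List with `annA`, `annB`, `merged`, `lincrnas`
#'   ([genome_annotation]s), `evidence` (tibble), `manifest` (tibble of
#'   planted discrepancies) and `predictions` (named list of expected module
#'   outputs).
#' @export
simulate_annotations <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  n <- cfg$n_genes
  set.seed(cfg$seed)

  ## ---- base gene structures (shared skeleton of A, B, merged) ----
  k <- sample(1:10, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cds_part <- sample(50:500, n, replace = TRUE)
  utr_len <- sample(100:1500, n, replace = TRUE)
  exon_lens <- purrr::map2(k, seq_len(n), function(ki, i) {
    lens <- if (ki > 1) sample(50:2000, ki - 1, replace = TRUE) else integer(0)
    c(lens, cds_part[i] + 3L + utr_len[i])
  })
  intron_lens <- purrr::map(k, function(ki) {
    if (ki > 1) sample(50:2000, ki - 1, replace = TRUE) else integer(0)
  })

  ## ---- category assignment ----
  take <- local({
    pool <- sample.int(n)   # shuffled indices; consumed front-to-back
    function(m, eligible = NULL) {
      cand <- if (is.null(eligible)) pool else intersect(pool, eligible)
      if (length(cand) < m) {
        abort("config error: not enough genes for the requested discrepancies")
      }
      picked <- cand[seq_len(m)]
      pool <<- setdiff(pool, picked)
      picked
    }
  })

  # block assignment: consecutive gene indices share a chromosome, so the
  # layout keeps index-adjacent genes genomically adjacent (fusion substrate)
  n_chrom <- max(1L, min(5L, ceiling(n / 50)))
  genes_per_chrom <- ceiling(n / n_chrom)
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% genes_per_chrom + 1L)

  # fusion pairs: consecutive indices on one chromosome (laid out adjacently)
  fusion_pairs <- list()
  if (cfg$n_fusion_transcripts > 0) {
    cand <- which(seq_len(n) < n & chrom_of == chrom_of[pmin(seq_len(n) + 1L, n)])
    cand <- cand[cand %% 2L == 1L]   # non-overlapping pairs
    first <- take(cfg$n_fusion_transcripts, cand)
    for (i in first) {
      take(1, i + 1L)
      strand[i + 1L] <- strand[i]
      fusion_pairs[[length(fusion_pairs) + 1L]] <- c(i, i + 1L)
    }
  }

  idx_split <- take(cfg$n_split_genes)
  idx_missing_A <- take(cfg$n_missing_from_A)
  idx_rescued <- take(cfg$n_rescued_A)
  idx_missing_B <- take(cfg$n_missing_from_B)
  idx_missing_M <- take(cfg$n_missing_from_merged)

  absent_A <- c(idx_split, idx_missing_A, idx_rescued)
  absent_B <- idx_missing_B
  n_in_A <- n - length(absent_A)
  n_in_B <- n - length(absent_B)

  idx_noutr_A <- take(round(cfg$frac_missing_utr3_A * n_in_A),
                      setdiff(seq_len(n), absent_A))
  idx_nostop_A <- take(round(cfg$frac_missing_stop_A * n_in_A),
                       setdiff(seq_len(n), absent_A))
  idx_noutr_B <- take(round(cfg$frac_missing_utr3_B * n_in_B),
                      setdiff(seq_len(n), absent_B))
  idx_nostop_B <- take(round(cfg$frac_missing_stop_B * n_in_B),
                       setdiff(seq_len(n), absent_B))
  idx_shift_B <- take(cfg$n_anchor_shift_B, which(k > 1))
  idx_longer_A <- take(cfg$n_utr_longer_A)
  idx_longer_B <- take(cfg$n_utr_longer_B)
  idx_same_ctrl <- take(cfg$n_same_controls)
  idx_dup_sym <- if (cfg$n_duplicate_symbols > 0) {
    matrix(take(2L * cfg$n_duplicate_symbols), ncol = 2L)
  } else matrix(integer(0), ncol = 2L)

  max_exon_len <- purrr::map_int(exon_lens, max)
  idx_xloc_host <- if (cfg$n_xloc[["redundant"]] > 0) {
    take(cfg$n_xloc[["redundant"]], which(max_exon_len >= 200L))
  } else integer(0)

  delta_A <- stats::setNames(rlogunif(length(idx_longer_A),
                                      cfg$delta_range[1], cfg$delta_range[2]),
                             idx_longer_A)
  delta_B <- stats::setNames(rlogunif(length(idx_longer_B),
                                      cfg$delta_range[1], cfg$delta_range[2]),
                             idx_longer_B)
  delta_ctrl <- stats::setNames(sample(1:50, length(idx_same_ctrl),
                                       replace = TRUE), idx_same_ctrl)

  # reference-set membership is decidable now; longer_C genes drawn from it
  refset_idx <- setdiff(seq_len(n),
                        c(absent_A, absent_B, idx_noutr_A, idx_noutr_B,
                          idx_shift_B))
  eligible_C <- setdiff(refset_idx, idx_missing_M)
  idx_longer_C <- if (cfg$n_utr_longer_C > 0) {
    if (length(eligible_C) < cfg$n_utr_longer_C) {
      abort("config error: not enough reference-set genes for n_utr_longer_C")
    }
    sort(sample(eligible_C, cfg$n_utr_longer_C))
  } else integer(0)
  delta_C <- stats::setNames(rlogunif(length(idx_longer_C),
                                      cfg$delta_range[1], cfg$delta_range[2]),
                             idx_longer_C)

  ## ---- symbols and IDs ----
  symbol <- sprintf("gene%04d", seq_len(n))
  if (nrow(idx_dup_sym) > 0) {
    for (j in seq_len(nrow(idx_dup_sym))) {
      symbol[idx_dup_sym[j, ]] <- sprintf("dupsym%02d", j)
    }
  }
  ida_g <- sprintf("ENSDARG%06d", seq_len(n))
  ida_t <- sprintf("ENSDART%06d", seq_len(n))
  idb_g <- sprintf("RSG%06d", seq_len(n))
  idb_t <- sprintf("RST%06d", seq_len(n))
  idm_g <- sprintf("MLOC%06d", seq_len(n))
  idm_t <- sprintf("TCONS%08d", seq_len(n))

  ## ---- genomic layout ----
  # room reserved on the 3' side of each gene for every planted extension
  ext_total <- rep(0L, n)
  for (i in idx_longer_A) ext_total[i] <- ext_total[i] + delta_A[[as.character(i)]]
  for (i in idx_longer_B) ext_total[i] <- ext_total[i] + delta_B[[as.character(i)]]
  for (i in idx_same_ctrl) ext_total[i] <- ext_total[i] + delta_ctrl[[as.character(i)]]
  for (i in idx_longer_C) ext_total[i] <- ext_total[i] + delta_C[[as.character(i)]]

  span <- purrr::map2_int(exon_lens, intron_lens,
                          function(e, ii) sum(e) + sum(ii))
  cursor <- stats::setNames(rep(1000L, n_chrom), paste0("chr", seq_len(n_chrom)))
  gene_start <- integer(n)  # leftmost coordinate of the unextended model
  gap <- sample(500:1000, n, replace = TRUE)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    left_room <- if (strand[i] == "-") ext_total[i] else 0L
    gene_start[i] <- cursor[[ch]] + left_room
    right_room <- if (strand[i] == "+") ext_total[i] else 0L
    cursor[[ch]] <- gene_start[i] + span[i] + right_room + gap[i]
  }

  ## ---- feature builders ----
  gene_rows <- function(i, gene_id, tx_id, source, delta = 0L,
                        drop_utr = FALSE, drop_stop = FALSE, shift = 0L,
                        biotype = "protein_coding") {
    make_sim_gene(
      chrom = chrom_of[i], strand = strand[i], start = gene_start[i],
      exon_lens = exon_lens[[i]], intron_lens = intron_lens[[i]],
      cds_part = cds_part[i], utr_len = utr_len[i],
      gene_id = gene_id, tx_id = tx_id, source = source,
      symbol = symbol[i], biotype = biotype,
      delta = delta, drop_utr = drop_utr, drop_stop = drop_stop,
      shift = shift
    )
  }

  featsA <- list(); featsB <- list(); featsM <- list()
  for (i in seq_len(n)) {
    dA <- if (i %in% idx_longer_A) delta_A[[as.character(i)]] else 0L
    dB <- if (i %in% idx_longer_B) delta_B[[as.character(i)]] else 0L
    dCtl <- if (i %in% idx_same_ctrl) delta_ctrl[[as.character(i)]] else 0L
    dA <- dA + dCtl   # same-class controls sit on the A side
    if (!(i %in% absent_A)) {
      featsA[[length(featsA) + 1L]] <- gene_rows(
        i, ida_g[i], ida_t[i], "simA", delta = dA,
        drop_utr = i %in% idx_noutr_A, drop_stop = i %in% idx_nostop_A
      )
    }
    if (!(i %in% absent_B)) {
      featsB[[length(featsB) + 1L]] <- gene_rows(
        i, idb_g[i], idb_t[i], "simB", delta = dB,
        drop_utr = i %in% idx_noutr_B, drop_stop = i %in% idx_nostop_B,
        shift = if (i %in% idx_shift_B) 7L else 0L
      )
    }
    if (!(i %in% c(idx_split, idx_missing_M))) {
      dM <- max(dA, dB) +
        (if (i %in% idx_longer_C) delta_C[[as.character(i)]] else 0L)
      featsM[[length(featsM) + 1L]] <- gene_rows(
        i, idm_g[i], idm_t[i], "simM", delta = dM
      )
    }
  }

  ## split genes: in B only, a second single-exon piece on another chromosome
  split_rows <- list()
  for (i in idx_split) {
    other <- paste0("chr", (match(chrom_of[i], names(cursor)) %% n_chrom) + 1L)
    if (other == chrom_of[i]) other <- chrom_of[i]  # single-chromosome layout
    piece_len <- 120L
    s2 <- cursor[[other]]
    cursor[[other]] <- s2 + piece_len + 600L
    split_rows[[length(split_rows) + 1L]] <- tibble(
      chrom = other, source = "simB", feature = "exon", kind = "exon",
      start = s2, end = s2 + piece_len - 1L, score = ".",
      strand = strand[i], frame = ".",
      gene_id = idb_g[i], transcript_id = paste0(idb_t[i], ".2"),
      attr_rest = paste0('gene_name "', symbol[i],
                         '"; gene_biotype "protein_coding";')
    )
  }
  featsB <- c(featsB, split_rows)

  ## rescue stubs: same-strand single-exon transcripts in A over genes absent
  ## from A (they must rescue those genes from the missing list)
  stub_rows <- list()
  for (j in seq_along(idx_rescued)) {
    i <- idx_rescued[j]
    ex1 <- first_exon_coords(chrom_of[i], strand[i], gene_start[i],
                             exon_lens[[i]], intron_lens[[i]])
    stub_rows[[length(stub_rows) + 1L]] <- tibble(
      chrom = chrom_of[i], source = "simA", feature = "exon", kind = "exon",
      start = ex1[1], end = ex1[2], score = ".", strand = strand[i],
      frame = ".", gene_id = sprintf("STUBG%03d", j),
      transcript_id = sprintf("STUBT%03d", j),
      attr_rest = paste0('gene_name "', symbol[i],
                         '"; gene_biotype "protein_coding";')
    )
  }
  featsA <- c(featsA, stub_rows)

  ## small RNAs: identical single-exon genes in A, B and merged
  sr_counts <- cfg$n_small_rna
  sr_rows_A <- list(); sr_rows_B <- list(); sr_rows_M <- list()
  sr_gene_ids_M <- character(0); sr_removed_M <- character(0)
  sr_i <- 0L
  for (bt in names(sr_counts)) {
    cnt <- sr_counts[[bt]]
    if (cnt == 0) next
    for (z in seq_len(cnt)) {
      sr_i <- sr_i + 1L
      ch <- paste0("chr", ((sr_i - 1L) %% n_chrom) + 1L)
      len <- sample(80:300, 1)
      s <- cursor[[ch]]
      cursor[[ch]] <- s + len + 600L
      st <- sample(c("+", "-"), 1)
      sym <- sprintf("%s-%02d", tolower(bt), z)
      row <- function(src, g, t) tibble(
        chrom = ch, source = src, feature = "exon", kind = "exon",
        start = s, end = s + len - 1L, score = ".", strand = st, frame = ".",
        gene_id = g, transcript_id = t,
        attr_rest = paste0('gene_name "', sym, '"; gene_biotype "', bt, '";')
      )
      sr_rows_A[[sr_i]] <- row("simA", sprintf("ENSDARG_SR%03d", sr_i),
                               sprintf("ENSDART_SR%03d", sr_i))
      sr_rows_B[[sr_i]] <- row("simB", sprintf("RSG_SR%03d", sr_i),
                               sprintf("RST_SR%03d", sr_i))
      gm <- sprintf("MLOC_SR%03d", sr_i)
      sr_rows_M[[sr_i]] <- row("simM", gm, sprintf("TCONS_SR%03d", sr_i))
      sr_gene_ids_M <- c(sr_gene_ids_M, gm)
      if (bt != "miRNA") sr_removed_M <- c(sr_removed_M, gm)
    }
  }
  featsA <- c(featsA, sr_rows_A)
  featsB <- c(featsB, sr_rows_B)
  featsM <- c(featsM, sr_rows_M)

  ## fusion transcripts bridging adjacent same-strand genes (merged only)
  fusion_rows <- list(); fusion_tx <- character(0)
  for (j in seq_along(fusion_pairs)) {
    p <- fusion_pairs[[j]]
    exL <- last_genomic_exon(chrom_of[p[1]], strand[p[1]], gene_start[p[1]],
                             exon_lens[[p[1]]], intron_lens[[p[1]]])
    exR <- first_exon_coords(chrom_of[p[2]], strand[p[2]], gene_start[p[2]],
                             exon_lens[[p[2]]], intron_lens[[p[2]]])
    txid <- sprintf("TCONS_FUS%03d", j)
    fusion_tx <- c(fusion_tx, txid)
    fusion_rows[[j]] <- tibble(
      chrom = chrom_of[p[1]], source = "simM", feature = "exon",
      kind = "exon",
      start = c(exL[1], exR[1]), end = c(exL[2], exR[2]), score = ".",
      strand = strand[p[1]], frame = ".",
      gene_id = idm_g[p[1]], transcript_id = txid,
      attr_rest = paste0('gene_name "', symbol[p[1]],
                         '"; gene_biotype "protein_coding";')
    )
  }
  featsM <- c(featsM, fusion_rows)

  ## novel XLOC loci (merged only) + lincRNA annotation + evidence table
  xl <- cfg$n_xloc
  xl_classes <- rep(names(xl), times = unlist(xl))
  xloc_rows <- list(); linc_rows <- list(); ev_rows <- list()
  xloc_decision <- list()
  for (j in seq_along(xl_classes)) {
    cls <- xl_classes[j]
    gid <- sprintf("XLOC_%06d", j)
    txid <- sprintf("XTCONS%06d", j)
    if (cls == "redundant") {
      host <- idx_xloc_host[sum(xl_classes[seq_len(j)] == "redundant")]
      hx <- widest_exon_coords(chrom_of[host], strand[host],
                               gene_start[host], exon_lens[[host]],
                               intron_lens[[host]])
      L <- min(hx[2] - hx[1] - 9L, sample(50:200, 1))
      rows <- tibble(
        chrom = chrom_of[host], source = "simM", feature = "exon",
        kind = "exon", start = hx[1] + 5L, end = hx[1] + 4L + L,
        score = ".", strand = strand[host], frame = ".",
        gene_id = gid, transcript_id = txid,
        attr_rest = 'gene_biotype "novel";'
      )
    } else {
      ch <- paste0("chr", ((j - 1L) %% n_chrom) + 1L)
      st <- sample(c("+", "-"), 1)
      nex <- if (cls == "multi_exon") sample(2:4, 1) else 1L
      lens <- sample(200:1000, nex, replace = TRUE)
      gaps <- if (nex > 1) sample(100:800, nex - 1, replace = TRUE) else integer(0)
      s0 <- cursor[[ch]]
      starts <- s0 + cumsum(c(0L, head(lens, -1) + gaps))
      cursor[[ch]] <- starts[nex] + lens[nex] + 600L
      rows <- tibble(
        chrom = ch, source = "simM", feature = "exon", kind = "exon",
        start = starts, end = starts + lens - 1L, score = ".", strand = st,
        frame = ".", gene_id = gid, transcript_id = txid,
        attr_rest = 'gene_biotype "novel";'
      )
      if (cls == "lincRNA_matched") {
        linc_rows[[length(linc_rows) + 1L]] <- rows |>
          mutate(source = "linc",
                 gene_id = sprintf("LINC%04d", j),
                 transcript_id = sprintf("LINCT%04d", j),
                 attr_rest = 'gene_biotype "lincRNA";')
      }
      if (cls == "evidence_backed") {
        ev_rows[[length(ev_rows) + 1L]] <- tibble(
          xloc_id = gid,
          protein_hit_confidence = sample(c("exact", "high", "moderate"), 1),
          species_hit = sample(c("zebrafish", "human", "both"), 1)
        )
      }
      if (cls == "single_exon_no_evidence" && j %% 2L == 0L) {
        ev_rows[[length(ev_rows) + 1L]] <- tibble(
          xloc_id = gid,
          protein_hit_confidence = sample(c("low", "none"), 1),
          species_hit = "none"
        )
      }
    }
    xloc_rows[[j]] <- rows
    xloc_decision[[j]] <- tibble(
      xloc_id = gid,
      decision = switch(cls,
        redundant = "redundant",
        single_exon_no_evidence = "drop",
        "retain"
      ),
      planted_class = cls
    )
  }
  featsM <- c(featsM, xloc_rows)

  if (!is.null(cfg$chrom_sizes)) {
    over <- names(cursor)[cursor > (cfg$chrom_sizes[names(cursor)] %||% Inf)]
    if (length(over) > 0) {
      abort(paste0("config error: chromosome(s) too small for requested genes: ",
                   paste(over, collapse = ", ")))
    }
  }

  annA <- genome_annotation(bind_rows(featsA), label = "simA")
  annB <- genome_annotation(bind_rows(featsB), label = "simB")
  merged <- genome_annotation(bind_rows(featsM), label = "simM")
  lincrnas <- genome_annotation(
    if (length(linc_rows)) bind_rows(linc_rows) else tibble(),
    label = "lincRNA"
  )
  evidence <- if (length(ev_rows)) bind_rows(ev_rows) else
    tibble(xloc_id = character(), protein_hit_confidence = character(),
           species_hit = character())
  xloc_tbl <- if (length(xloc_decision) > 0) bind_rows(xloc_decision) else
    tibble(xloc_id = character(), decision = character(),
           planted_class = character())

  ## ---- manifest ----
  man <- function(type, id, detail = NA_character_, param = NA_real_) {
    if (length(id) == 0) return(NULL)
    tibble(type = type, id = id, detail = detail, param = param)
  }
  manifest <- bind_rows(
    man("missing_from_A", idb_g[idx_missing_A]),
    man("rescued_A", idb_g[idx_rescued], detail = "stub overlap in A"),
    man("split_gene_B", idb_g[idx_split], detail = "second piece on other chromosome"),
    man("missing_from_B", ida_g[idx_missing_B]),
    man("missing_from_merged", idm_g[idx_missing_M]),
    man("missing_utr3_A", ida_g[idx_noutr_A]),
    man("missing_stop_A", ida_g[idx_nostop_A]),
    man("missing_utr3_B", idb_g[idx_noutr_B]),
    man("missing_stop_B", idb_g[idx_nostop_B]),
    man("anchor_shift_B", idb_g[idx_shift_B], param = 7),
    man("utr_longer_A", ida_g[idx_longer_A], param = unname(delta_A)),
    man("utr_longer_B", idb_g[idx_longer_B], param = unname(delta_B)),
    man("same_control", ida_g[idx_same_ctrl], param = unname(delta_ctrl)),
    man("utr_longer_C", idm_g[idx_longer_C], param = unname(delta_C)),
    man("fusion_transcript", fusion_tx),
    man("duplicate_symbol",
        if (nrow(idx_dup_sym)) ida_g[as.vector(t(idx_dup_sym))] else character(0),
        detail = if (nrow(idx_dup_sym))
          rep(sprintf("dupsym%02d", seq_len(nrow(idx_dup_sym))), each = 2L)
        else character(0)),
    man("small_rna_removed", sr_removed_M),
    if (nrow(xloc_tbl) > 0) {
      tibble(type = paste0("xloc_", xloc_tbl$planted_class),
             id = xloc_tbl$xloc_id, detail = xloc_tbl$decision,
             param = NA_real_)
    }
  )

  ## ---- predictions (manifest arithmetic only) ----
  n_sr <- sum(unlist(sr_counts))
  base_utr <- utr_len
  lenA <- base_utr
  lenA[idx_longer_A] <- lenA[idx_longer_A] + unname(delta_A)
  lenA[idx_same_ctrl] <- lenA[idx_same_ctrl] + unname(delta_ctrl)
  lenB <- base_utr
  lenB[idx_longer_B] <- lenB[idx_longer_B] + unname(delta_B)
  class_AB <- classify_relative_length(lenA[refset_idx], lenB[refset_idx])

  predictions <- list(
    audit_A = list(
      n_genes_total = n_in_A + n_sr + length(idx_rescued),
      n_genes_cds = n_in_A,
      n_cds_missing_stop = length(idx_nostop_A),
      n_cds_missing_utr3 = length(idx_noutr_A)
    ),
    audit_B = list(
      n_genes_total = n_in_B + n_sr,
      n_genes_cds = n_in_B,
      n_cds_missing_stop = length(idx_nostop_B),
      n_cds_missing_utr3 = length(idx_noutr_B)
    ),
    refset = list(
      n_rows = length(refset_idx),
      n_same = sum(class_AB == "same"),
      n_longer_A = sum(class_AB == "longer_A"),
      n_longer_B = sum(class_AB == "longer_B"),
      gene_keys = sort(ida_g[refset_idx])
    ),
    refset_C = list(
      n_matched_C = length(setdiff(refset_idx, idx_missing_M)),
      n_longer_C = length(idx_longer_C)
    ),
    confirmed_missing_from_A = sort(idb_g[c(idx_missing_A, idx_split)]),
    confirmed_missing_from_B = sort(ida_g[idx_missing_B]),
    merged_missing_vs_A = sort(ida_g[idx_missing_M]),
    merged_missing_vs_B = sort(idb_g[c(idx_missing_M, idx_split)]),
    fusion_transcripts = sort(fusion_tx),
    small_rna_removed = sort(sr_removed_M),
    xloc_decisions = xloc_tbl |> select("xloc_id", "decision") |>
      arrange(.data$xloc_id),
    n_symbol_conflicts_after_curation = 2L * nrow(idx_dup_sym),
    split_kept_chrom = stats::setNames(chrom_of[idx_split], idb_g[idx_split])
  )

  list(annA = annA, annB = annB, merged = merged, lincrnas = lincrnas,
       evidence = evidence, manifest = manifest, predictions = predictions,
       config = cfg)
}

## ---- coordinate helpers (transcript 5'->3' structure onto the genome) ----

# genomic exon coordinates for a simulated gene; exon_lens runs 5'->3'
sim_exon_coords <- function(strand, start, exon_lens, intron_lens) {
  glens <- if (strand == "+") exon_lens else rev(exon_lens)
  gintr <- if (strand == "+") intron_lens else rev(intron_lens)
  starts <- start + cumsum(c(0L, head(glens, -1) + gintr))
  cbind(start = starts, end = starts + glens - 1L)
}

first_exon_coords <- function(chrom, strand, start, exon_lens, intron_lens) {
  co <- sim_exon_coords(strand, start, exon_lens, intron_lens)
  unname(co[1, ])   # genomically leftmost exon
}

last_genomic_exon <- function(chrom, strand, start, exon_lens, intron_lens) {
  co <- sim_exon_coords(strand, start, exon_lens, intron_lens)
  unname(co[nrow(co), ])
}

widest_exon_coords <- function(chrom, strand, start, exon_lens, intron_lens) {
  co <- sim_exon_coords(strand, start, exon_lens, intron_lens)
  unname(co[which.max(co[, "end"] - co[, "start"]), ])
}

# Full feature rows (exon/CDS/stop_codon/three_prime_utr) for one simulated
# protein-coding gene. delta extends the 3' UTR; shift displaces the terminal
# exon's 5' boundary (and the CDS edge with it).
make_sim_gene <- function(chrom, strand, start, exon_lens, intron_lens,
                          cds_part, utr_len, gene_id, tx_id, source,
                          symbol, biotype, delta = 0L, drop_utr = FALSE,
                          drop_stop = FALSE, shift = 0L) {
  k <- length(exon_lens)
  co <- sim_exon_coords(strand, start, exon_lens, intron_lens)
  attrs <- paste0('gene_name "', symbol, '"; gene_biotype "', biotype, '";')
  kinds <- character(0); ss <- integer(0); ee <- integer(0)
  frames <- character(0)
  add <- function(kind, s, e, frame = ".") {
    kinds <<- c(kinds, kind); ss <<- c(ss, as.integer(s))
    ee <<- c(ee, as.integer(e)); frames <<- c(frames, frame)
  }

  if (strand == "+") {
    term <- k            # genomic row index of the 3'-terminal exon
    co[term, "end"] <- co[term, "end"] + delta
    co[term, "start"] <- co[term, "start"] + shift
    for (r in seq_len(k)) add("exon", co[r, 1], co[r, 2])
    if (k > 1) for (r in seq_len(k - 1)) add("CDS", co[r, 1], co[r, 2], "0")
    cds_s <- co[term, "start"]
    cds_e <- cds_s + (cds_part - shift) - 1L
    add("CDS", cds_s, cds_e, "0")
    if (!drop_stop) add("stop_codon", cds_e + 1L, cds_e + 3L, "0")
    if (!drop_utr) add("three_prime_utr", cds_e + 4L, co[term, "end"])
  } else {
    term <- 1L           # leftmost genomic exon is the 3' end
    co[term, "start"] <- co[term, "start"] - delta
    co[term, "end"] <- co[term, "end"] - shift
    for (r in seq_len(k)) add("exon", co[r, 1], co[r, 2])
    if (k > 1) for (r in 2:k) add("CDS", co[r, 1], co[r, 2], "0")
    cds_e <- co[term, "end"]
    cds_s <- cds_e - (cds_part - shift) + 1L
    add("CDS", cds_s, cds_e, "0")
    if (!drop_stop) add("stop_codon", cds_s - 3L, cds_s - 1L, "0")
    if (!drop_utr) add("three_prime_utr", co[term, "start"], cds_s - 4L)
  }
  m <- length(kinds)
  structure(
    list(
      chrom = rep(chrom, m), source = rep(source, m), feature = kinds,
      kind = kinds, start = ss, end = ee, score = rep(".", m),
      strand = rep(strand, m), frame = frames,
      gene_id = rep(gene_id, m), transcript_id = rep(tx_id, m),
      attr_rest = rep(attrs, m)
    ),
    class = "data.frame", row.names = c(NA_integer_, -m)
  )
}
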