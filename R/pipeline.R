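#' Run the full merge-curation pipeline
#'
#' Applies the curation steps to an assembly-merged annotation in order:
#' \enumerate{
#'   \item flag and remove fusion transcripts bridging two reference genes;
#'   \item remove small-RNA genes (never miRNAs);
#'   \item triage novel XLOC loci, dropping unsupported and redundant ones;
#'   \item assign nomenclature from the reference annotations (priority
#'     `ens` > `refseq` > novel XLOC placeholder), recording conflicts;
#'   \item add back reference genes confirmed missing from the merged
#'     annotation (small-RNA genes deliberately removed in step 2 are not
#'     re-added); genes split across chromosomes contribute their larger
#'     piece;
#'   \item assign stable LL gene IDs and build the gene-information table.
#' }
#'
#' @param merged A [genome_annotation] (e.g. a Cuffmerge-style union).
#' @param ens,refseq Reference [genome_annotation]s.
#' @param evidence,lincrnas Optional inputs for [classify_xloc()].
#' @param crosswalks Optional named list of external-ID crosswalks for
#'   [build_gene_info()]; Ensembl/NCBI links derived from coordinate matching
#'   are filled in automatically and user-supplied crosswalks take precedence.
#' @param min_overlap_bp Fusion-overlap threshold (nt).
#' @param small_rna_biotypes Biotypes removed in step 2.
#' @param single_exon_frac Single-exon full-match fraction for the matcher.
#' @return List with `annotation` (curated, LL IDs assigned), `gene_info`,
#'   `fusion_flags`, `small_rna_removed`, `xloc_decisions`, `conflicts`,
#'   `added`, `skipped`, `ll_table`, and `summary` (one-row tibble with the
#'   gene-count conservation bookkeeping:
#'   `n_merged - n_removed + n_added = n_curated`).
#' @examples
#' sim <- simulate_annotations(fixture_config(n_genes = 40, seed = 5))
#' res <- curate_annotation(sim$merged, sim$annA, sim$annB,
#'                          evidence = sim$evidence, lincrnas = sim$lincrnas)
#' res$summary
#' @export
curate_annotation <- function(merged, ens, refseq,
                              evidence = NULL, lincrnas = NULL,
                              crosswalks = list(),
                              min_overlap_bp = 30,
                              small_rna_biotypes = c("rRNA", "snRNA",
                                                     "snoRNA", "sRNA",
                                                     "miscRNA"),
                              single_exon_frac = 0.8) {
  n_merged <- nrow(ann_genes(merged))

  fusions <- detect_fusion_transcripts(merged, list(ens, refseq),
                                       min_overlap_bp = min_overlap_bp)
  rm_fus <- remove_transcripts(merged, fusions$transcript_id)

  rm_sr <- suppressWarnings(
    remove_small_rna(rm_fus$annotation, biotypes = small_rna_biotypes)
  )

  xloc <- classify_xloc(rm_sr$annotation, evidence, lincrnas,
                        refs = list(ens, refseq),
                        single_exon_frac = single_exon_frac)
  xloc_gone <- xloc$xloc_id[xloc$decision %in% c("drop", "redundant")]
  cur <- ann_drop_genes(rm_sr$annotation, xloc_gone)

  rep_e <- match_annotations(query = cur, reference = ens,
                             single_exon_frac = single_exon_frac)
  rep_r <- match_annotations(query = cur, reference = refseq,
                             single_exon_frac = single_exon_frac)
  nom <- assign_nomenclature(cur, ens, refseq, rep_e, rep_r)

  small_rna_of <- function(ref) {
    g <- ann_genes(ref)
    g$gene_id[!is.na(g$biotype) & g$biotype %in% small_rna_biotypes]
  }
  miss_e <- setdiff(confirm_missing_genes(rep_e), small_rna_of(ens))
  miss_r <- setdiff(confirm_missing_genes(rep_r), small_rna_of(refseq))
  ab <- add_back_missing(nom$annotation,
                         missing = list(ens = miss_e, refseq = miss_r),
                         refs = list(ens = ens, refseq = refseq))

  ll <- assign_ll_ids(ab$annotation)

  auto_xw <- list(
    ensembl = rep_e$gene_pairs |>
      transmute(gene_id = .data$query_gene,
                external_id = .data$reference_gene),
    ncbi = rep_r$gene_pairs |>
      transmute(gene_id = .data$query_gene,
                external_id = .data$reference_gene)
  )
  for (nm in names(crosswalks)) auto_xw[[nm]] <- crosswalks[[nm]]
  gene_info <- build_gene_info(ll$annotation, auto_xw, rep_e, rep_r)

  n_curated <- nrow(ann_genes(ll$annotation))
  n_removed <- length(rm_fus$removed_genes) + length(rm_sr$removed_genes) +
    length(xloc_gone)
  list(
    annotation = ll$annotation,
    gene_info = gene_info,
    fusion_flags = fusions,
    small_rna_removed = rm_sr$removed_genes,
    xloc_decisions = xloc,
    conflicts = nom$conflicts,
    added = ab$added,
    skipped = ab$skipped,
    ll_table = ll$table,
    summary = tibble(
      n_merged = n_merged,
      n_fusion_transcripts_removed = nrow(fusions),
      n_genes_lost_with_fusions = length(rm_fus$removed_genes),
      n_small_rna_removed = length(rm_sr$removed_genes),
      n_xloc_removed = length(xloc_gone),
      n_added_back = nrow(ab$added),
      n_skipped_add_back = nrow(ab$skipped),
      n_curated = n_curated
    )
  )
}
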