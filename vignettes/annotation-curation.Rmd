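---
title: "Auditing, comparing and curating transcriptome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing, comparing and curating transcriptome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoforge)
library(dplyr)
```

## The problem

Two annotations of the same genome assembly routinely disagree in ways that
matter for RNA-seq. First, 3' UTR models are incomplete: a coding gene may
lack any transcript with an annotated 3' UTR, or carry a UTR kilobases
shorter than its true transcript end. Because oligo-dT-primed bulk libraries
and droplet scRNA-seq chemistries concentrate reads at transcript 3' ends,
reads landing in an unannotated UTR are silently discarded during
quantification, depressing the measured expression of exactly those genes
and shifting differential-expression calls. Second, each annotation simply
misses thousands of gene models the other carries, so gene-level results
depend on which annotation was chosen. annoforge provides the coordinate
arithmetic to measure both defect classes and a mechanized workflow to
repair a merged annotation.

## The data model

Everything operates on a `genome_annotation`: a label plus a tibble of GTF
feature rows (1-based, fully closed intervals; length is `end - start + 1`).
The gene/transcript hierarchy is implied by the `gene_id` and
`transcript_id` attributes, so GTF dialects without explicit gene or
transcript lines parse identically. Feature semantics come from GTF column 3
exactly as written: a 3' UTR exists where a `three_prime_utr` (or
`3UTR`/`UTR3`) row exists. The stop codon is not part of the 3' UTR; where a
dialect lacks UTR rows entirely, `derive_utr3_from_cds()` can reconstruct
them as the exonic sequence strictly 3' of the stop codon, but it is off by
default everywhere so that audits report what each annotation literally
says. Genes asserted on several chromosomes are kept and flagged as split
rather than rejected; the curation step consumes the flag.

## Completeness audit

`audit_completeness()` collapses feature presence to gene level - a gene
"has" a stop codon or 3' UTR if *any* of its transcripts carries at least
one segment of that kind - which avoids double-counting alternatively
spliced multi-exon UTRs. A coding gene is any gene with at least one CDS
segment; biotype labels are not required, so the audit is dialect-agnostic.

```{r audit}
sim <- simulate_annotations(fixture_config(n_genes = 150, seed = 1))
audit_completeness(sim$annA)
```

## The matched reference gene set

Comparing 3' UTR lengths across annotations requires deciding which
transcript over there corresponds to this gene over here, without trusting
either side's gene symbols. The anchor used is the 5' boundary of the
terminal 3'-UTR-containing exon - the exon start on the plus strand, the
exon end on the minus strand. That coordinate is a fixed point of the
comparison: two annotations that disagree about how far a 3' UTR extends
still agree on where its terminal exon begins, because that boundary is set
by the splice acceptor, not by the annotated transcript end.

Per gene of the driver annotation, the representative transcript is the one
with the longest 3' UTR (ties to the lexicographically smallest transcript
ID - a deterministic stand-in for an arbitrary choice). The other
annotation contributes its per-transcript terminal UTR exons, collapsed
when coordinates are identical; matching is by exact (chromosome, strand,
anchor) equality. Exactness avoids ambiguous many-to-many joins; when two
entries do share an anchor the longer-UTR entry is paired and the row is
flagged ambiguous. Matched pairs are classified `same` / `longer_A` /
`longer_B`, where "longer" means more than 50 nt longer - a threshold wide
enough to ignore trivial end-trimming differences between pipelines while
catching biologically meaningful extensions; a delta of exactly 50 nt is
still `same`. A third annotation (e.g. a curated merge) is incorporated by
the same anchor key and classified against the longer of the two lengths
already in the row.

```{r refset}
rs <- build_reference_set(sim$annA, sim$annB) |>
  incorporate_annotation(sim$merged)
glance(rs)
```

## Transcript matching and missing genes

`match_annotations()` performs coordinate-based structural comparison with
gffcompare-style class codes: `=` (identical intron chains; terminal exon
boundaries free to differ), `c` (contained), `j` (some shared junction),
`o` (same-strand exonic overlap), `x` (antisense overlap only), `u`
(nothing). Two choices the code family leaves open are pinned down
explicitly: a single-exon pair is `=` when the reciprocal overlap reaches
0.8 of the shorter transcript (configurable), and features with strand `.`
are compared on both strands but can never be `=`. Ties among equally
classed query transcripts go to the larger exonic overlap, then the smaller
transcript ID.

A reference gene is *confirmed missing* from the query only when every one
of its transcripts is `x` or `u`: any same-strand overlap anywhere rescues
the gene. This re-search step matters - a gene with one matched and five
unmatched isoforms is not a missing gene, and on the synthetic fixtures the
rescue rule is exercised by planted stub transcripts that overlap otherwise
absent genes.

## Curation of a merged annotation

`curate_annotation()` runs the repair pipeline in a fixed order:

1. **Fusion removal.** Assembly merging produces spurious transcripts whose
   exons bridge two adjacent same-strand genes, corrupting quantification
   and nomenclature. A transcript is flagged when, within any single
   reference annotation, its exons overlap exons of two or more distinct
   same-strand genes by at least 30 nt each (the threshold is a parameter;
   30 nt ignores micro-overlaps from boundary jitter while catching any
   real exon sharing). Removal is idempotent: a second scan flags nothing.
2. **Small-RNA removal.** Genes with biotype rRNA, snRNA, snoRNA, sRNA or
   miscRNA are dropped; miRNA genes are always kept, whatever the set says.
3. **Novel-locus triage.** XLOC loci are `redundant` when any transcript is
   `=`/`c` against a reference (they duplicate an existing model), else
   retained if they have an exact/high/moderate-confidence protein-homology
   hit ("low" fails), or structural overlap (`=`, `c`, `j`, `o`) with a
   published lincRNA set, or more than one exon; single-exon loci with no
   support are dropped.
4. **Nomenclature.** Symbols import by matched gene with priority primary
   reference > secondary reference > `XLOC_` placeholder. Conflicts are
   recorded, never silently resolved: one merged gene matching two
   differently named reference genes, or one symbol landing on two merged
   loci.
5. **Add-back.** Reference genes confirmed missing from the merge are
   copied in verbatim (no exon re-fitting) with an `added_back_*`
   provenance attribute. Small RNAs deliberately removed in step 2 are not
   re-added. A gene split across chromosomes contributes only the piece
   with the larger total exonic span (ties to the piece with the 3' UTR) -
   exonic span rather than transcript length, because the stray piece is
   typically a single orphaned 5' exon. A gene whose exons would overlap an
   existing curated gene on the same strand is skipped, so the add-back
   cannot re-create a fusion; the overlap index grows as genes are added,
   which also stops the same locus arriving twice from two references.
6. **Stable IDs.** Every gene receives an `LL<n>` identifier assigned in
   (chromosome, start, gene ID) order - deterministic across runs - and
   written into each GTF line, linking the annotation to the
   gene-information table of external IDs, symbols and match-confidence
   notes (`full_transcript_match` for an `=` link, otherwise
   `gene_coordinate_overlap`).

The run conserves gene counts by construction:
`merged - removed + added = curated`, and the summary reports every term.

```{r curate}
res <- curate_annotation(sim$merged, sim$annA, sim$annB,
                         evidence = sim$evidence, lincrnas = sim$lincrnas)
res$summary
```

## What the synthetic generator emulates

`simulate_annotations()` builds paired annotations "A" (Ensembl-like) and
"B" (RefSeq-like) plus a merged assembly, planting every discrepancy class
the toolkit detects and recording each in a manifest. The `$predictions`
element carries the exact expected output of every module, computed from
the planted bookkeeping alone - never by running the modules - so the
generator is an end-to-end oracle: the test suite checks module output
against these predictions across 20 randomized configurations of 100-1000
genes.

Default rates are the ones observed between public zebrafish annotations:
~18% of coding genes missing any 3' UTR and ~6% missing a stop codon on the
A side (6% and 1% on B); ~15% / 8% of genes with a >50 nt longer 3' UTR in
A / B; ~10% / 6.5% of genes absent from A / B. Gene structures draw 1-10
exons of 50-2000 nt with intergenic gaps of at least 500 nt plus room
reserved for planted extensions, so no accidental overlaps contaminate the
planted truth. UTR deltas are log-uniform in [60, 5000] nt - straddling the
50 nt threshold from above only - with separate 1-50 nt "same-class"
controls sitting at the boundary.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: sequence content (coordinates only), overlapping
or nested real gene loci, alternative isoforms per gene beyond the planted
cases, trans-spliced or single-exon-heavy gene families, and the long tail
of real GTF dialect quirks. The full-scale comparison of public zebrafish
annotations additionally depends on matching gffcompare's default semantics
in every corner case, which the class-code subset here does not promise.

## Numerical and design choices

* Coordinates are GTF-native: 1-based, fully closed; all lengths are
  `end - start + 1`.
* Alt-contig filtering uses the pattern `"_alt|_random"` by default and is
  configurable, since conventions differ between assemblies.
* The driver annotation's gene IDs key the reference set, mirroring the
  construction that starts from the annotation with explicit UTR terminal
  exons.
* The B-side match is restricted to B's own terminal-UTR-exon set (not any
  transcript), which is the stricter reading; sensitivity to this choice
  can be probed by passing a pre-filtered annotation.
* Fixture sizes in the test suite span 100-1000 genes; the acceptance
  script reports on 500 genes. These sizes exercise every code path while
  keeping the oracle checks exact.
* Ties everywhere break by sort order (transcript ID, gene ID, symbol), so
  repeated runs - and runs with any `--threads` setting - are
  byte-identical.

## Known limitations

* Only the six class codes above are implemented; gffcompare's `i`, `e`,
  `p`, `s`, `y`, `r` codes and its `.tracking`/`.loci` outputs are not.
* Symbol-conflict handling is report-only; resolving a conflict correctly
  often needs curator judgment, so the package records evidence instead of
  guessing.
* GFF3 input, FASTA handling and assembly validation are out of scope; use
  rtracklayer or GenomicFeatures to convert first.
* `derive_utr3_from_cds()` assumes the stop codon is annotated; transcripts
  without one are flagged rather than guessed.
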