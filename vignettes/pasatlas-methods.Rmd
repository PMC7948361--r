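---
title: "pasatlas: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pasatlas: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasatlas)
```

# Overview

`pasatlas` builds an atlas of polyadenylation sites (PASs) from 3′ end
sequencing reads, annotates and quantifies alternative PAS usage, and
measures motif and protein-binding geometry around the resulting sites.
Every stage is deterministic given a seed, and a built-in synthetic-data
generator provides ground truth so the whole pipeline can be validated
at desk scale.

This vignette documents the models, conventions and default parameters
the package implements, and the limitations of each.

# Conventions

* All internal coordinates are **1-based inclusive**, the native
  convention of the Bioconductor ranges infrastructure. BED/bedGraph
  files are converted to their 0-based half-open convention at the file
  boundary (via `rtracklayer`); GTF stays 1-based inclusive.
* *Upstream* and *downstream* are always meant in the direction of
  transcription: on the minus strand, downstream means decreasing
  genomic coordinate. All coordinate logic is strand-mirror symmetric
  and tested as such.
* RNA motifs (`UGUA`, CSE hexamers) are matched as DNA on the coding
  strand (`U` → `T`), with full IUPAC degeneracy.

# PAS discovery from 3′ end reads

## Read preparation

`prepare_reads()` applies, in order:

1. **Quality trimming** from both read ends: terminal bases with a
   Phred score below 16 are removed.
2. **Trailing poly(A) detection** (`trim_polya()`): the read is scanned
   from its 3′ end with a 5-nt sliding window, allowing at most one
   non-adenosine per window; the scan stops at the first window
   containing two or more non-A bases, leading non-A bases are returned
   to the read body, and the accepted region is trimmed off if and only
   if it contains at least 10 adenosines (the *A10* criterion).
3. **PCR deduplication**: reads sharing an 8-nt UMI and the same
   aligned coordinate (or the same trimmed sequence, when no
   coordinates are available) are collapsed to one. Reads without a UMI
   are dropped with a warning.

## Cleavage events, artifact filter, clustering

The **cleavage event** of a poly(A) read is the nucleotide 1 nt
downstream (transcription direction) of the poly(A)-trimmed read 3′
end.

Internal-priming artifacts — oligo(dT) annealing to genomic A-runs
instead of a true poly(A) tail — are removed with a genome-derived
filter: `find_genomic_a_stretches()` reports every 10-nt window with at
most 2 non-A (plus strand; non-T on the minus strand), merged per
strand, and `filter_internal_priming()` discards any event that an
A-stretch overlaps or that has a stretch starting within 5 nt
downstream.

Events pooled over samples are clustered per contig and strand in
transcription order (`cluster_cleavage_events()`): a cluster is seeded
with the most upstream unassigned position and extended with the next
downstream position while it lies within 25 nt of the running cluster
median. The median is taken over member positions *with event
multiplicity*; an even count gives the mean of the central pair.
Clusters are then resized to **15-nt windows** centered on the mode
event position, ties broken towards the most upstream position
(`define_pas_windows()`).

## Quantification and filtering

For each window and sample, `quantify_and_filter()` recomputes:

* `CE` — cleavage events inside the 15-nt window, averaged over
  replicates per condition (`CE_average`);
* `PU` — percent usage, `CE` divided by all cleavage events of the
  complete gene (gene span extended 50 nt downstream) × 100;
* `TPM` — `CE / 0.015 / (library_size / 1e6)`, with the library size
  the sample's total trimmed, deduplicated, artifact-filtered cleavage
  events; `TPM_maximum` is the per-gene maximum of `TPM_average`.

A window is retained iff, taking the maximum across conditions,
`CE_average > 4` **and** `PU_average > 5` **and** the gene-level
`TPM_maximum > 0.25` (all strict).

# Annotation

* **Gene and region** (`assign_gene_and_region()`): windows are
  assigned by the overlap of their center with gene spans; centers
  overlapping more than one gene are removed; centers 1–50 nt
  downstream of exactly one gene are assigned to that gene's 3′UTR.
  Region precedence is 3′UTR > intron > single region kind > "Other".
* **Typing** (`classify_pas_types()`): per gene in transcription order,
  the most upstream PAS is proximal (`pPAS`), the most downstream
  distal (`dPAS`), anything between `oPAS`; a gene's only PAS is
  `sPAS`.
* **CSE assignment** (`assign_cse()`): the 50 nt upstream of each
  cleavage site are searched for the 18 configured CSE hexamers
  (shipped as editable data in
  `system.file("extdata/cse_hexamers.tsv", package = "pasatlas")`),
  with the hierarchy `AAUAAA` > `AUUAAA` > the remaining hexamer whose
  start is closest to the PAS (ties alphabetical).
* **External APA callers** (`match_dapars()`, `threshold_apa()`,
  `overlap_fisher()`): an external PAS matches an atlas PAS of the same
  gene and type when it lies at most 250 nt upstream / 50 nt downstream
  of it; the closest candidate wins and each external PAS is used once.
  Significant 3′UTR change requires `FDR <= 0.1` and
  `|ΔPDUI| >= 0.05` (inclusive); gene-set overlaps are tested with
  Fisher's exact test.

# Motif statistics

`motif_metaprofile()` reports, per offset in a ±300-nt window, the
fraction of PASs with at least one motif start at that offset, plus a
loess smoothing (local quadratic regression, span 0.1 of the window).
`motif_background_zscore()` compares a target PAS set against 100
size-matched resamples (without replacement) from a background pool:
`z = (target − mean_bg) / sd_bg` per offset, two-sided normal P values,
Benjamini–Hochberg correction, flags at `FDR <= 0.01`. Offsets with
zero background sd are excluded and reported.

`tandem_ugua()` implements the paired-window tandem-UGUA geometry:
two windows are incremented simultaneously around the cleavage site
(`Win_size` 1–75 for mode *enclosing*, 1–150 for *preceded* and
*followed*); a PAS qualifies at `Win_size` W when two distinct UGUA
starts satisfy the mode's ranges (enclosing: first in `[−W, −4]`,
second in `[−3, W−3]`; preceded: both in `[−W, −4]`; followed: both in
`[1, W−3]`). The cumulative qualifying fraction and each PAS's minimum
inter-UGUA distance are reported.

# Crosslink (iCLIP-style) statistics

* **Extraction** (`extract_crosslinks()`): the crosslink event sits
  1 nt upstream of the read start (truncation convention).
* **Significant sites** (`call_significant_xlinks()`): per gene, the
  gene's events are redistributed uniformly over its positions 100
  times; `FDR(h)` = mean permuted number of positions with count ≥ h /
  observed number; positions whose height has `FDR < 0.05` are called.
* **k-mers** (`kmer_zscore()`): 5-mers are counted in the two flanks
  −30..−5 and +5..+30 nt around each significant crosslink (the
  crosslink-proximal ±4 nt excluded, flanks clipped at gene edges);
  z-scores come from 100 within-gene shuffles of the significant
  positions.
* **Metaprofile** (`pas_metaprofile()`): summed crosslink counts per
  offset in −400..+100 around the PAS, normalized first by the number
  of anchors, then by the library's total positions with crosslink
  events.
* **Two-library comparison** (`compare_profiles()`): per offset, a
  pooled two-proportions z-test on the anchored counts of the two
  libraries with totals = library event totals, after rescaling library
  B by `f` = positions-with-events(A) / positions-with-events(B); BH
  across offsets, flags at `FDR <= 0.01`.
* **Matched background** (`profile_background_z()`): the resampling
  z-procedure applied to normalized crosslink profiles.

# Synthetic data generator

`simulate_genome()` builds a multi-gene contig (default 20 genes, both
strands), each gene with a 5′UTR, two CDS segments around one intron,
and a 3′UTR hosting 1–4 true PASs (frequencies 0.55/0.27/0.11/0.07);
about 10% of genes place their distal PAS 1–50 nt downstream of the
annotated end. Each PAS gets a CSE hexamer drawn from the configured
frequency table (start 14–32 nt upstream), one planted `UGUA` 50 nt
upstream, and a usage weight ≥ 0.15 (weights sum to 1 per gene).
Transcript-sense pure-A stretches of 12–15 nt are planted inside each
3′UTR (seeding internal-priming artifacts) and in intergenic space.

Two constructions keep the planted truth unambiguous: the ±8 nt around
each cleavage site is kept free of transcript-sense adenosines (so
poly(A) trimming cannot absorb templated bases and shift the inferred
cleavage site), and accidental hexamer occurrences inside each 50-nt
CSE search window are mutated away.

`simulate_mace_reads()` emits, per sample, ~20 genuine reads per PAS
(multinomially split by usage weight) with Gaussian cleavage jitter
(sd 1 nt, rounded) and a non-templated 12–20-nt poly(A) tail, plus
internal-priming reads whose sequence runs 12 nt into a planted
A-stretch — their aligned (post-trim) 3′ end is the base just upstream
of the run — at 30% of reads under the default study conditions, and
PCR duplicates (10%).
`simulate_crosslinks()` draws Poisson background events over gene spans
plus a per-PAS Gaussian enrichment bump centered 75 nt upstream.

# Pipeline

`pipeline_config()` collects every threshold with the defaults above;
`run_pipeline()` executes the stages `simulate → call_pas → annotate →
motif → xlink` in dependency order, writes all outputs plus a
`manifest.json` with MD5 hashes, and is bit-identical under identical
config and seed. An enabled stage whose dependency is disabled raises
an error naming both stages.

# Limitations

* No read alignment: simulated reads carry their alignment truth; real
  data must arrive as aligned 3′-end positions (BED) plus FASTQ for
  trimming statistics.
* The significant-crosslink FDR procedure is a reconstruction
  (within-gene uniform permutation with height-based FDR), not a
  re-implementation of any specific published tool.
* The two-proportions comparison uses library *event* totals as the
  denominators and the positions-based scaling factor; both choices are
  explicit in `compare_profiles()`.
* k-mers are counted unweighted (each occurrence once per flank
  window).
* The synthetic generator uses the simplest noise models that exercise
  the pipeline (Poisson counts, rounded Gaussian jitter); it is not a
  sequencing-error simulator.
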