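# pasatlas

Build, annotate and interrogate an atlas of polyadenylation sites
(PASs) from 3′ end sequencing data — with a fully deterministic
synthetic-data generator that provides ground truth for every stage.

Most protein-coding genes carry more than one PAS, and regulated choice
between proximal and distal sites (alternative polyadenylation, APA)
reshapes 3′UTR length, and with it mRNA stability, localization and
translation. Splicing factors such as SR proteins influence that choice
by binding near the cleavage site. Analyzing this requires a chain of
specialized steps: calling cleavage sites from oligo(dT)-primed 3′ end
reads (which suffer from internal-priming artifacts at genomic A-runs),
clustering noisy cleavage positions into discrete sites, quantifying
and filtering them, classifying each site by its position within the
gene and its cleavage/polyadenylation signal hexamer, and relating the
sites to binding motifs (UGUA) and protein–RNA crosslink events from
iCLIP-style experiments. `pasatlas` implements that chain end to end.

## What the package does

* **PAS discovery** — trailing poly(A) detection with an A10 criterion,
  Phred-16 quality trimming, UMI deduplication, cleavage-event
  extraction (1 nt downstream of the trimmed 3′ end), a genome-derived
  internal-priming filter, median-linkage clustering (≤ 25 nt), 15-nt
  windows on the mode position, and strict cleavage-event / percent-
  usage / TPM filters (CE > 4, PU > 5, TPM > 0.25).
* **Annotation** — gene and region assignment with 3′UTR > intron
  precedence, sites up to 50 nt past the annotated end rescued as
  3′UTR, single/proximal/other/distal typing, hierarchical CSE hexamer
  assignment (AAUAAA > AUUAAA > closest of 16 variants) in the 50 nt
  upstream, and matching/thresholding of external APA-caller output
  (FDR ≤ 0.1, |ΔPDUI| ≥ 0.05) with Fisher overlap tests.
* **Motif statistics** — IUPAC-aware motif metaprofiles around PASs
  with loess smoothing, size-matched background resampling z-scores
  with BH correction, and the tandem-UGUA paired-window analysis
  (enclosing / preceded / followed).
* **Crosslink statistics** — crosslink extraction (1 nt upstream of
  read starts), per-gene permutation FDR for significant positions,
  flank k-mer enrichment z-scores, two-step-normalized metaprofiles,
  and scaled two-proportions comparison of two libraries.
* **Synthetic data** — a seeded generator producing a multi-gene
  genome, annotation, truth tables (PAS positions, types, hexamers,
  planted A-stretches, motifs), 3′ end reads with poly(A) tails, PCR
  duplicates and internal-priming artifacts, and crosslink tracks with
  a planted enrichment bump.
* **Pipeline** — `pipeline_config()` / `run_pipeline()` orchestrate all
  stages, write FASTA/GTF/BED/bedGraph/TSV/JSON outputs and an MD5
  manifest, and are bit-identical under a fixed seed.

See the vignette source (`vignettes/pasatlas-methods.Rmd`) for the full
model and parameter documentation.

## Worked example

```r
library(pasatlas)

cfg <- pipeline_config(seed = 42, out_dir = file.path(tempdir(), "demo"),
                       n_genes = 8L, reads_per_pas = 15L)
res <- run_pipeline(cfg)

atlas <- res$results$atlas
head(atlas[, c("gene_id", "strand", "center", "region", "pas_type",
               "cse", "CE_average.ctrl", "PU_average.ctrl")])
#>   gene_id strand center region pas_type    cse CE_average.ctrl PU_average.ctrl
#> 1 gene001      +   1173   3UTR     pPAS AAUAAA             8.5        18.88889
#> 2 gene001      +   1277   3UTR     oPAS AUUAAA            22.0        48.88889
#> 3 gene001      +   1374   3UTR     dPAS AAUAAA            14.5        32.22222
#> 4 gene002      -   1655   3UTR     sPAS UAUAAA            15.0       100.00000
#> 5 gene003      -   2931   3UTR     dPAS AUUAAA            10.5        35.00000
#> 6 gene003      -   3015   3UTR     pPAS AAUAAA            19.5        65.00000

str(res$log$call_pas)
#> List of 8
#>  $ n_input                  : int 1700
#>  $ n_missing_umi            : int 0
#>  $ n_unusable               : int 0
#>  $ n_duplicates_removed     : int 156
#>  $ n_polya                  : int 1544
#>  $ n_events                 : int 337
#>  $ n_artifact_events_removed: int 32
#>  $ n_windows                : int 18
```

All 18 atlas windows land within 3 nt of a true planted PAS (18 of 18
truth sites recovered), the smoothed UGUA metaprofile peaks at offset
−51 (the motif is planted at −50), and the smoothed crosslink
metaprofile peaks at −75, exactly where the enrichment bump was
planted. Rows 5–6 show a minus-strand gene: sorted by genomic
coordinate, its distal PAS (smaller coordinate) precedes the proximal
one.

Individual stages are ordinary functions and can be used on their own,
e.g.:

```r
trim_polya("ACGTACGTAAAAAAAAAA")
#>    trimmed n_trailing_a is_polya usable
#> 1 ACGTACGT           10     TRUE   TRUE
```

## Installation and reproduction

The package uses only packages from CRAN and Bioconductor
(`Biostrings`, `rtracklayer`, `GenomicRanges`, `jsonlite`, …).

```sh
R CMD INSTALL .

# full test suite against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "pasatlas",
                               load_package = "installed")'

# end-to-end acceptance run (flat JSON report of headline quantities)
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

With `--seed 1` the acceptance run reports, among other quantities,
`pas_recovery_percent: 100`, `median_center_error_nt: 0`,
`artifact_windows_retained: 0`, `ugua_smoothed_peak_offset_nt: -50`
and `xlink_smoothed_peak_offset_nt: -75`. All randomness flows from
the `--seed` argument; repeated runs with the same seed are
bit-identical.
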