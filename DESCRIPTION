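Package: pasatlas
Title: Polyadenylation-Site Atlas Construction and Alternative
    Polyadenylation Analytics from 3' End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an atlas of polyadenylation sites (PASs) from 3' end
    sequencing (MACE-seq-like) reads: trailing poly(A) detection with a
    sliding-window rule, internal-priming artifact removal against genomic
    A-stretches, median-linkage clustering of cleavage events, 15-nt
    cleavage windows with CE/PU/TPM quantification and filtering, gene and
    region assignment, proximal/distal PAS typing, and hierarchical central
    sequence element (CSE) hexamer annotation. Integrates external APA
    caller tables (PDUI), computes motif metaprofiles around PASs with
    matched-background resampling z-scores, tandem-UGUA geometry, and iCLIP
    crosslink-track statistics (significant-site permutation FDR, k-mer
    enrichment, normalized PAS metaprofiles, two-proportions comparisons).
    Ships a fully deterministic synthetic-data generator so every stage can
    be validated at desk scale against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
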