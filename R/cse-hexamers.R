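#' Default central sequence element (CSE) hexamer list
#'
#' The 18 hexameric polyadenylation signals commonly reported for
#' mammalian PASs, shipped as editable data
#' (`inst/extdata/cse_hexamers.tsv`). The `freq` column gives the
#' relative frequencies used by the synthetic-data generator when
#' planting signals; the canonical AAUAAA dominates, followed by AUUAAA,
#' UAUAAA, AAGAAA and AAUAUA.
#'
#' @param path optional path to an alternative two-column TSV
#'   (`hexamer`, `freq`); hexamers are written in RNA alphabet.
#' @return data.frame with columns `hexamer` (RNA), `dna` (DNA
#'   equivalent) and `freq` (normalized to sum 1).
#' @export
cse_hexamers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cse_hexamers.tsv", package = "pasatlas")
  }
  h <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("hexamer", "freq") %in% names(h)))
  h$hexamer <- toupper(h$hexamer)
  if (anyDuplicated(h$hexamer)) stop("duplicate hexamers", call. = FALSE)
  if (!all(nchar(h$hexamer) == 6L)) stop("hexamers must have length 6",
                                         call. = FALSE)
  h$dna <- rna_to_dna(h$hexamer)
  h$freq <- h$freq / sum(h$freq)
  h[, c("hexamer", "dna", "freq")]
}
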