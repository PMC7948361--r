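#' Read a genome FASTA file
#'
#' Loads a genome as a [Biostrings::DNAStringSet], uppercased, with the
#' alphabet restricted to A/C/G/T/N and unique contig names (the first
#' whitespace-delimited word of each FASTA header).
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per contig.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(g))) {
    stop("duplicate contig names in ", path, call. = FALSE)
  }
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  bad <- Biostrings::alphabetFrequency(g)[, setdiff(colnames(Biostrings::alphabetFrequency(g)), c("A", "C", "G", "T", "N")), drop = FALSE]
  if (any(bad > 0)) {
    stop("genome contains letters outside {A,C,G,T,N}", call. = FALSE)
  }
  g
}

#' Write a genome FASTA file
#'
#' @param genome a `DNAStringSet` (or named character vector of sequences).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
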