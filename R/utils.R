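# Strand-aware coordinate helpers. Transcription direction: "+" strand
# downstream = increasing genomic coordinate, "-" strand downstream =
# decreasing genomic coordinate.

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(strand)
}

#' Shift positions downstream in transcription direction
#'
#' @param pos integer vector of genomic positions (1-based).
#' @param n number of nucleotides to shift (negative = upstream).
#' @param strand character vector of "+"/"-" (recycled).
#' @return shifted positions.
#' @keywords internal
tx_shift <- function(pos, n, strand) {
  check_strand(strand)
  pos + ifelse(strand == "+", 1L, -1L) * n
}

# Signed offset of `pos` relative to `anchor` in transcription direction
# (positive = downstream of the anchor).
tx_offset <- function(pos, anchor, strand) {
  check_strand(strand)
  ifelse(strand == "+", 1L, -1L) * (pos - anchor)
}

# Order index so that positions come in transcription order (most
# upstream first).
tx_order <- function(pos, strand) {
  check_strand(strand)
  if (length(strand) == 1L) strand <- rep(strand, length(pos))
  order(ifelse(strand == "+", pos, -pos))
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract the transcript-oriented (5'->3') sequence covering genomic
# interval [lo, hi] on `contig`; clipped to the contig. Returns the
# character sequence plus the genomic coordinates actually used.
extract_tx_seq <- function(genome, contig, strand, lo, hi) {
  check_strand(strand)
  len <- Biostrings::width(genome)[match(contig, names(genome))]
  if (is.na(len)) stop("unknown contig: ", contig, call. = FALSE)
  lo2 <- max(1L, lo)
  hi2 <- min(len, hi)
  if (lo2 > hi2) {
    return(list(seq = "", lo = NA_integer_, hi = NA_integer_,
                truncated = TRUE))
  }
  s <- as.character(Biostrings::subseq(genome[[contig]], lo2, hi2))
  if (strand == "-") s <- revcomp(s)
  list(seq = s, lo = lo2, hi = hi2, truncated = (lo2 != lo || hi2 != hi))
}

# RNA motif written with U -> DNA pattern on the coding strand.
rna_to_dna <- function(x) gsub("U", "T", toupper(x))

dna_to_rna <- function(x) gsub("T", "U", toupper(x))

# Weighted median of integer positions where each position carries a
# multiplicity (event count). Even total -> mean of the central pair.
weighted_median <- function(pos, count) {
  stopifnot(length(pos) == length(count), all(count >= 1))
  o <- order(pos)
  pos <- pos[o]; count <- count[o]
  n <- sum(count)
  cum <- cumsum(count)
  if (n %% 2L == 1L) {
    k <- (n + 1L) / 2L
    pos[which(cum >= k)[1L]]
  } else {
    k1 <- n / 2L
    k2 <- k1 + 1L
    (pos[which(cum >= k1)[1L]] + pos[which(cum >= k2)[1L]]) / 2
  }
}

# Benjamini-Hochberg over a vector that may contain NAs (excluded and
# returned as NA).
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
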