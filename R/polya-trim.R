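# Trailing poly(A) detection and read preparation.

#' Detect and trim a trailing poly(A) tail with a 5-nt sliding window
#'
#' Scans a read from its 3' end towards the 5' end, extending the
#' candidate trailing region one base at a time; the scan stops at the
#' first 5-nt window (within the candidate region) that contains two or
#' more non-adenosines, i.e. every window inside the accepted region has
#' at most one non-A. Leading non-A bases of the accepted region are
#' given back to the read body, and the region is trimmed off if and
#' only if it contains at least 10 adenosines (the A10 criterion).
#'
#' @param seq character vector of read sequences over A/C/G/T/N.
#' @return data.frame with `trimmed` (sequence after trimming),
#'   `n_trailing_a` (adenosine count of the accepted trailing region),
#'   `is_polya` (TRUE when the A10 criterion was met and the tail
#'   trimmed) and `usable` (FALSE when fewer than 5 nt remain).
#' @export
trim_polya <- function(seq) {
  res <- lapply(seq, function(s) {
    s <- toupper(s)
    x <- strsplit(s, "")[[1]]
    L <- length(x)
    nonA <- x != "A"
    # extend the suffix leftwards; k = accepted suffix length
    k <- 0L
    while (k < L) {
      cand <- k + 1L
      if (cand >= 5L) {
        win <- (L - cand + 1L):(L - cand + 5L)
        if (sum(nonA[win]) >= 2L) break
      }
      k <- cand
    }
    # give leading non-A bases of the region back to the read body
    while (k > 0L && nonA[L - k + 1L]) k <- k - 1L
    n_a <- if (k > 0L) sum(!nonA[(L - k + 1L):L]) else 0L
    if (n_a >= 10L) {
      trimmed <- substr(s, 1L, L - k)
      list(trimmed = trimmed, n_trailing_a = n_a, is_polya = TRUE,
           usable = nchar(trimmed) >= 5L)
    } else {
      list(trimmed = s, n_trailing_a = n_a, is_polya = FALSE,
           usable = nchar(s) >= 5L)
    }
  })
  data.frame(
    trimmed = vapply(res, `[[`, "", "trimmed"),
    n_trailing_a = vapply(res, `[[`, integer(1), "n_trailing_a"),
    is_polya = vapply(res, `[[`, logical(1), "is_polya"),
    usable = vapply(res, `[[`, logical(1), "usable"),
    stringsAsFactors = FALSE)
}

# Trim low-quality bases (Phred < cutoff) from both ends of one read.
quality_trim_one <- function(seq, qual, cutoff) {
  ph <- as.integer(charToRaw(qual)) - 33L
  L <- length(ph)
  lo <- 1L
  while (lo <= L && ph[lo] < cutoff) lo <- lo + 1L
  hi <- L
  while (hi >= lo && ph[hi] < cutoff) hi <- hi - 1L
  if (lo > hi) list(seq = "", qual = "")
  else list(seq = substr(seq, lo, hi), qual = substr(qual, lo, hi))
}

#' Prepare 3' end reads: quality trim, poly(A) trim, UMI deduplication
#'
#' Applies, in order: quality trimming from both read ends (bases with
#' Phred score below `phred_cutoff`), trailing poly(A) detection and
#' trimming ([trim_polya()]), and PCR-duplicate removal. Duplicates are
#' reads sharing the same UMI and the same aligned coordinate (when
#' `positions` is supplied) or the same UMI and trimmed sequence
#' otherwise; one representative survives. Reads without a UMI are
#' dropped with a warning. The operation is idempotent: preparing
#' already-prepared reads changes nothing.
#'
#' @param reads data.frame with at least `read_id`, `umi`, `seq`;
#'   optional `qual` (Phred+33 string).
#' @param positions optional data.frame mapping `read_id` to `contig`,
#'   `strand`, `position` (aligned 3' end), e.g. from the simulator's
#'   truth BED.
#' @param phred_cutoff quality threshold (default 16).
#' @return list with `reads` (surviving reads plus `trimmed`,
#'   `n_trailing_a`, `is_polya` columns and, when positions were given,
#'   the coordinate columns) and `log` (counts: input, missing UMI,
#'   unusable, duplicates removed, poly(A) reads).
#' @export
prepare_reads <- function(reads, positions = NULL, phred_cutoff = 16) {
  n_in <- nrow(reads)
  miss <- is.na(reads$umi) | !nzchar(reads$umi %||% "")
  if (any(miss)) {
    warning("dropping ", sum(miss), " read(s) without UMI", call. = FALSE)
    reads <- reads[!miss, , drop = FALSE]
  }
  if ("qual" %in% names(reads) && nrow(reads)) {
    for (i in seq_len(nrow(reads))) {
      qt <- quality_trim_one(reads$seq[i], reads$qual[i], phred_cutoff)
      reads$seq[i] <- qt$seq
      reads$qual[i] <- qt$qual
    }
  }
  tp <- trim_polya(reads$seq)
  reads$trimmed <- tp$trimmed
  reads$n_trailing_a <- tp$n_trailing_a
  reads$is_polya <- tp$is_polya
  n_unusable <- sum(!tp$usable)
  reads <- reads[tp$usable, , drop = FALSE]

  if (!is.null(positions)) {
    idx <- match(reads$read_id, positions$read_id)
    reads$contig <- positions$contig[idx]
    reads$strand <- positions$strand[idx]
    reads$position <- positions$position[idx]
    key <- paste(reads$umi, reads$contig, reads$strand, reads$position)
  } else {
    key <- paste(reads$umi, reads$trimmed)
  }
  dup <- duplicated(key)
  n_dup <- sum(dup)
  reads <- reads[!dup, , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads,
       log = list(n_input = n_in, n_missing_umi = sum(miss),
                  n_unusable = n_unusable, n_duplicates_removed = n_dup,
                  n_polya = sum(reads$is_polya)))
}
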