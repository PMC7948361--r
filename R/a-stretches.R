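# Genomic A-stretch discovery and internal-priming artifact filtering.

#' Find homopolymeric A-stretches in a genome
#'
#' Direct genome scan equivalent to aligning A10 with up to two
#' mismatches: every 10-nt window with at most 2 non-A (forward strand)
#' or at most 2 non-T (minus strand, i.e. A-rich in transcript sense) is
#' reported, overlapping windows are merged per strand, and each merged
#' interval is trimmed so it starts and ends on the homopolymer base
#' (a stretch never begins or ends with a mismatch base).
#'
#' @param genome a `DNAStringSet`.
#' @param min_a minimum A count per 10-nt window (default 8, i.e. two
#'   errors allowed).
#' @return data.frame with `contig`, `strand`, `start`, `end` of merged
#'   stretches (1-based inclusive).
#' @export
find_genomic_a_stretches <- function(genome, min_a = 8L) {
  out <- list()
  for (ct in names(genome)) {
    s <- genome[[ct]]
    if (length(s) < 10L) next
    for (strand in c("+", "-")) {
      letter <- if (strand == "+") "A" else "T"
      cnt <- Biostrings::letterFrequencyInSlidingView(s, 10L, letter)[, 1]
      hit <- which(cnt >= min_a)
      if (!length(hit)) next
      ir <- IRanges::reduce(IRanges::IRanges(hit, width = 10L))
      # trim ends to the homopolymer base itself
      is_l <- Biostrings::letterFrequencyInSlidingView(s, 1L, letter)[, 1] == 1L
      starts <- IRanges::start(ir)
      ends <- IRanges::end(ir)
      for (q in seq_along(starts)) {
        while (!is_l[starts[q]]) starts[q] <- starts[q] + 1L
        while (!is_l[ends[q]]) ends[q] <- ends[q] - 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, strand = strand,
        start = starts, end = ends,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$strand, res$start), , drop = FALSE]
}

#' Remove internal-priming cleavage events
#'
#' A cleavage event is removed when, on the same contig and strand, an
#' A-stretch overlaps the event position or begins within `adjacency_nt`
#' nucleotides downstream of it (in transcription direction): this is
#' the geometry oligo(dT) mispriming at a genomic A-run produces.
#'
#' @param events cleavage events (`contig`, `strand`, `position`, ...).
#' @param stretches output of [find_genomic_a_stretches()].
#' @param adjacency_nt adjacency window in nt (default 5).
#' @return list with `events` (retained rows) and `n_removed`.
#' @export
filter_internal_priming <- function(events, stretches, adjacency_nt = 5L) {
  if (!nrow(events) || !nrow(stretches)) {
    return(list(events = events, n_removed = 0L))
  }
  remove <- logical(nrow(events))
  for (key in unique(paste(events$contig, events$strand))) {
    ei <- which(paste(events$contig, events$strand) == key)
    si <- which(paste(stretches$contig, stretches$strand) == key)
    if (!length(si)) next
    st <- stretches[si, , drop = FALSE]
    strand <- events$strand[ei[1]]
    pos <- events$position[ei]
    # transcript-sense 5' start of each stretch
    tx_start <- if (strand == "+") st$start else st$end
    for (k in seq_along(ei)) {
      p <- pos[k]
      overlap <- any(st$start <= p & p <= st$end)
      downstream <- if (strand == "+") {
        any(tx_start > p & tx_start <= p + adjacency_nt)
      } else {
        any(tx_start < p & tx_start >= p - adjacency_nt)
      }
      remove[ei[k]] <- overlap || downstream
    }
  }
  list(events = events[!remove, , drop = FALSE],
       n_removed = sum(remove))
}

#' Derive cleavage events from prepared reads
#'
#' The cleavage event of a poly(A) read is the nucleotide 1 nt
#' downstream (transcription direction) of the poly(A)-trimmed read 3'
#' end. Only reads flagged as poly(A) reads contribute. Events are
#' aggregated per sample and position.
#'
#' @param prepared output of [prepare_reads()] with coordinate columns
#'   (`contig`, `strand`, `position` = trimmed 3' end).
#' @return data.frame of cleavage events: `contig`, `strand`, `position`,
#'   `sample_id`, `count`.
#' @export
cleavage_events_from_reads <- function(prepared) {
  r <- prepared$reads
  r <- r[r$is_polya & !is.na(r$position), , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(contig = character(), strand = character(),
                      position = integer(), sample_id = character(),
                      count = integer()))
  }
  r$event <- tx_shift(r$position, 1L, r$strand)
  sid <- if ("sample_id" %in% names(r)) r$sample_id else "sample1"
  agg <- aggregate(list(count = rep(1L, nrow(r))),
                   by = list(contig = r$contig, strand = r$strand,
                             position = r$event, sample_id = sid),
                   FUN = sum)
  agg <- agg[order(agg$contig, agg$strand, agg$position, agg$sample_id), ]
  rownames(agg) <- NULL
  agg[, c("contig", "strand", "position", "sample_id", "count")]
}
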