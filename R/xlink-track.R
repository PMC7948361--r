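# Crosslink tracks: per-position iCLIP crosslink-event counts for one
# library.

#' Crosslink track constructor
#'
#' @param library library id (single string).
#' @param events data.frame with `contig`, `strand`, `position`,
#'   `count` (counts >= 1, one row per position).
#' @return object of class `crosslink_track` with the events table and
#'   the library summaries `n_events` (total events) and `n_positions`
#'   (positions with >= 1 event).
#' @export
crosslink_track <- function(library, events) {
  stopifnot(is.character(library), length(library) == 1L,
            all(c("contig", "strand", "position", "count") %in%
                  names(events)))
  check_strand(events$strand)
  if (any(events$count < 1)) {
    stop("crosslink counts must be >= 1 at stored positions",
         call. = FALSE)
  }
  key <- paste(events$contig, events$strand, events$position)
  if (anyDuplicated(key)) {
    stop("duplicate (contig, strand, position) rows in crosslink track",
         call. = FALSE)
  }
  events <- events[order(events$contig, events$strand, events$position),
                   c("contig", "strand", "position", "count"),
                   drop = FALSE]
  rownames(events) <- NULL
  out <- list(library = library, events = events,
              n_events = sum(events$count), n_positions = nrow(events))
  class(out) <- "crosslink_track"
  out
}

#' @export
print.crosslink_track <- function(x, ...) {
  cat("crosslink track '", x$library, "': ", x$n_events,
      " events at ", x$n_positions, " positions\n", sep = "")
  invisible(x)
}

#' Extract crosslink events from deduplicated read starts
#'
#' The crosslink event of an iCLIP read sits 1 nt upstream
#' (transcription direction) of the read start: start 100 on "+" gives
#' a crosslink at 99, start 100 on "-" gives 101. Counts are aggregated
#' per position; crosslinks falling off the contig are dropped with a
#' warning.
#'
#' @param read_starts data.frame with `contig`, `strand`, `start` (read
#'   5' position), one row per deduplicated read.
#' @param genome a `DNAStringSet` (for contig bounds).
#' @param library library id for the resulting track.
#' @return a [crosslink_track].
#' @export
extract_crosslinks <- function(read_starts, genome, library = "iclip") {
  stopifnot(all(c("contig", "strand", "start") %in% names(read_starts)))
  check_strand(read_starts$strand)
  pos <- tx_shift(read_starts$start, -1L, read_starts$strand)
  lens <- Biostrings::width(genome)[match(read_starts$contig,
                                          names(genome))]
  ok <- !is.na(lens) & pos >= 1L & pos <= lens
  if (any(!ok)) {
    warning(sum(!ok), " crosslink position(s) off-contig, dropped",
            call. = FALSE)
  }
  df <- data.frame(contig = read_starts$contig[ok],
                   strand = read_starts$strand[ok],
                   position = pos[ok], count = 1L,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- aggregate(count ~ contig + strand + position, df, sum)
  }
  crosslink_track(library, df)
}

# Counts of a track at given (contig, strand, position) triples.
track_counts_at <- function(track, contig, strand, position) {
  key <- paste(contig, strand, position)
  tkey <- paste(track$events$contig, track$events$strand,
                track$events$position)
  cnt <- track$events$count[match(key, tkey)]
  cnt[is.na(cnt)] <- 0L
  cnt
}
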