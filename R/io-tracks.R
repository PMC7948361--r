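# Track readers/writers. Internal coordinates are 1-based inclusive; BED
# and bedGraph conversion to/from 0-based half-open is delegated to
# rtracklayer at the file boundary.

sort_events <- function(events, warn = TRUE) {
  o <- order(events$contig, events$position)
  if (!identical(o, seq_len(nrow(events)))) {
    if (warn) {
      warning("input not sorted by contig/position; sorting internally",
              call. = FALSE)
    }
    events <- events[o, , drop = FALSE]
    rownames(events) <- NULL
  }
  events
}

#' Write single-nucleotide events to a BED6 file
#'
#' Each event (a cleavage event or crosslink event) occupies one
#' nucleotide; the BED name column carries the sample/library id and the
#' score column the event count. Unsorted input is sorted internally with
#' a warning.
#'
#' @param events data.frame with columns `contig`, `strand`, `position`
#'   (1-based), `sample_id`, `count`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  events <- sort_events(events)
  gr <- GenomicRanges::GRanges(
    seqnames = events$contig,
    ranges = IRanges::IRanges(events$position, width = 1L),
    strand = events$strand)
  S4Vectors::mcols(gr)$name <- as.character(events$sample_id)
  S4Vectors::mcols(gr)$score <- as.numeric(events$count)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read single-nucleotide events from a BED6 file
#'
#' Inverse of [write_events_bed()]; the round trip preserves counts
#' exactly.
#'
#' @param path BED6 path (name = sample id, score = count).
#' @return data.frame with columns `contig`, `strand`, `position`,
#'   `sample_id`, `count`.
#' @export
read_events_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    position = GenomicRanges::start(gr),
    sample_id = as.character(S4Vectors::mcols(gr)$name),
    count = as.integer(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE)
}

#' Write per-position counts to a bedGraph file
#'
#' @param events data.frame with `contig`, `position` (1-based), `count`.
#'   Strand is not representable in bedGraph; filter per strand first.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(events, path) {
  o <- order(events$contig, events$position)
  events <- events[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = events$contig,
    ranges = IRanges::IRanges(events$position, width = 1L))
  S4Vectors::mcols(gr)$score <- as.numeric(events$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write PAS windows to a BED6 file
#'
#' Each 15-nt window becomes one BED interval; name = window id, score =
#' 0, strand carried through.
#'
#' @param windows data.frame with `contig`, `strand`, `start`, `end`,
#'   `window_id`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_pas_bed <- function(windows, path) {
  o <- order(windows$contig, windows$start)
  windows <- windows[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = windows$contig,
    ranges = IRanges::IRanges(windows$start, windows$end),
    strand = windows$strand)
  S4Vectors::mcols(gr)$name <- as.character(windows$window_id)
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write/read a generic pasatlas TSV table
#'
#' Plain tab-separated tables with a header line and stable column order;
#' used for the PAS atlas, profiles and truth tables. Coordinates stay
#' 1-based inclusive.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
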