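# Median-linkage clustering of cleavage events and 15-nt PAS windows.

#' Cluster cleavage events by iterative median extension
#'
#' Events (pooled across samples) are processed per contig and strand in
#' transcription order. A cluster is seeded with the most upstream
#' unassigned position and extended with the next downstream position
#' while that position lies within `max_dist` nt of the current cluster
#' median; otherwise the cluster is closed and a new one seeded. The
#' median is taken over member positions counted with event multiplicity
#' (an even total gives the mean of the central pair).
#'
#' @param events data.frame `contig`, `strand`, `position`, `count`
#'   (pooled; use [pool_events()] to sum over samples).
#' @param max_dist maximum distance to the running median (default 25).
#' @return data.frame with one row per event position: original columns
#'   plus `cluster_id`.
#' @export
cluster_cleavage_events <- function(events, max_dist = 25L) {
  if (!nrow(events)) {
    events$cluster_id <- character(0)
    return(events)
  }
  out <- list()
  cl <- 0L
  for (key in unique(paste(events$contig, events$strand))) {
    sub <- events[paste(events$contig, events$strand) == key, ,
                  drop = FALSE]
    strand <- sub$strand[1]
    sub <- sub[tx_order(sub$position, strand), , drop = FALSE]
    member_pos <- integer(0); member_cnt <- integer(0)
    ids <- integer(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      p <- sub$position[i]
      if (!length(member_pos)) {
        cl <- cl + 1L
        member_pos <- p; member_cnt <- sub$count[i]
      } else {
        med <- weighted_median(member_pos, member_cnt)
        if (abs(p - med) <= max_dist) {
          member_pos <- c(member_pos, p)
          member_cnt <- c(member_cnt, sub$count[i])
        } else {
          cl <- cl + 1L
          member_pos <- p; member_cnt <- sub$count[i]
        }
      }
      ids[i] <- cl
    }
    sub$cluster_id <- sprintf("cl%05d", ids)
    out[[length(out) + 1L]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pool cleavage events across samples
#'
#' @param events per-sample cleavage events.
#' @return events summed over samples per position.
#' @export
pool_events <- function(events) {
  if (!nrow(events)) {
    return(data.frame(contig = character(), strand = character(),
                      position = integer(), count = integer()))
  }
  agg <- aggregate(count ~ contig + strand + position, events, sum)
  agg <- agg[order(agg$contig, agg$strand, agg$position), ]
  rownames(agg) <- NULL
  agg
}

#' Resize clusters to 15-nt PAS windows centered on the cleavage mode
#'
#' The window center (the reported cleavage site) is the position with
#' the highest event count within the cluster; ties are broken towards
#' the most upstream position in transcription direction. The window
#' spans center +/- 7 nt (15 nt total).
#'
#' @param clustered output of [cluster_cleavage_events()].
#' @param half_width half window width in nt (default 7, i.e. 15-nt
#'   windows).
#' @return data.frame with one row per cluster: `window_id`, `contig`,
#'   `strand`, `center`, `start`, `end`, `n_events`.
#' @export
define_pas_windows <- function(clustered, half_width = 7L) {
  if (!nrow(clustered)) {
    return(data.frame(window_id = character(), contig = character(),
                      strand = character(), center = integer(),
                      start = integer(), end = integer(),
                      n_events = integer()))
  }
  rows <- lapply(split(clustered, clustered$cluster_id), function(sub) {
    strand <- sub$strand[1]
    best <- sub$count == max(sub$count)
    cand <- sub$position[best]
    center <- if (strand == "+") min(cand) else max(cand)
    data.frame(window_id = sub$cluster_id[1], contig = sub$contig[1],
               strand = strand, center = center,
               start = center - half_width, end = center + half_width,
               n_events = sum(sub$count), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
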