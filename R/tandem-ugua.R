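# Tandem-UGUA geometry: cumulative fraction of PASs carrying two
# distinct UGUA starts in paired windows incremented around the
# cleavage site.

# Minimal window size at which a pair of UGUA starts (s1 <= s2, tx
# offsets) qualifies under a mode, or NA when it never can:
#   enclosing: s1 in [-W, -4] and s2 in [-3, W-3]  -> W = max(-s1, s2+3)
#   preceded:  both in [-W, -4]                    -> W = -s1
#   followed:  both in [1, W-3]                    -> W = s2 + 3
pair_min_win <- function(s1, s2, mode) {
  switch(mode,
    enclosing = if (s1 <= -4L && s2 >= -3L) max(-s1, s2 + 3L) else NA_integer_,
    preceded = if (s2 <= -4L) -s1 else NA_integer_,
    followed = if (s1 >= 1L) s2 + 3L else NA_integer_)
}

#' Tandem-UGUA window profile around a PAS anchor set
#'
#' Two windows are incremented simultaneously around each cleavage site
#' (`Win_size` 1-75 nt for mode "enclosing", 1-150 nt for "preceded"
#' and "followed"). A PAS qualifies at `Win_size` W when two distinct
#' UGUA start offsets s1 <= s2 satisfy the mode's ranges: enclosing
#' requires s1 in `[-W, -4]` and s2 in `[-3, W-3]`; preceded requires
#' both in `[-W, -4]`; followed requires both in `[1, W-3]`. The
#' cumulative fraction of qualifying PASs is reported over the grid
#' (non-decreasing by construction), together with each PAS's minimum
#' distance between two qualifying UGUA starts.
#'
#' @param anchors data.frame with `contig`, `strand`, `center`.
#' @param genome a `DNAStringSet`.
#' @param mode one of "enclosing", "preceded", "followed".
#' @return list of class `tandem_ugua_profile` with `mode`, `profile`
#'   (data.frame `win_size`, `fraction`) and `per_pas` (data.frame
#'   `min_win_size`, `min_distance`; `NA` for PASs that never qualify).
#' @export
tandem_ugua <- function(anchors, genome,
                        mode = c("enclosing", "preceded", "followed")) {
  mode <- match.arg(mode)
  if (!nrow(anchors)) stop("need at least one anchor", call. = FALSE)
  grid_max <- if (mode == "enclosing") 75L else 150L

  min_win <- rep(NA_integer_, nrow(anchors))
  min_dist <- rep(NA_integer_, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    st <- sort(unique(scan_motif(genome, anchors$contig[i],
                                 anchors$strand[i], anchors$center[i],
                                 "UGUA", half_window = grid_max)))
    if (length(st) < 2L) next
    for (a in seq_len(length(st) - 1L)) {
      for (b in (a + 1L):length(st)) {
        w <- pair_min_win(st[a], st[b], mode)
        if (is.na(w) || w > grid_max) next
        if (is.na(min_win[i]) || w < min_win[i]) min_win[i] <- w
        d <- st[b] - st[a]
        if (is.na(min_dist[i]) || d < min_dist[i]) min_dist[i] <- d
      }
    }
  }

  grid <- seq_len(grid_max)
  fraction <- vapply(grid, function(w) {
    mean(!is.na(min_win) & min_win <= w)
  }, numeric(1))
  out <- list(mode = mode,
              profile = data.frame(win_size = grid, fraction = fraction),
              per_pas = data.frame(min_win_size = min_win,
                                   min_distance = min_dist))
  class(out) <- "tandem_ugua_profile"
  out
}

#' @export
print.tandem_ugua_profile <- function(x, ...) {
  n <- nrow(x$per_pas)
  cat("tandem-UGUA profile (", x$mode, "): ", n, " PASs, ",
      sum(!is.na(x$per_pas$min_win_size)),
      " qualifying at Win_size ", max(x$profile$win_size), "\n", sep = "")
  invisible(x)
}
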