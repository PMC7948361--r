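# PAS-anchored crosslink metaprofiles, two-library comparison and
# matched-background z-scores.

# Per-offset summed crosslink counts of a track around a set of
# anchors (tx offsets win[1]..win[2]).
anchor_offset_counts <- function(track, anchors, win) {
  offs <- win[1]:win[2]
  acc <- numeric(length(offs))
  for (i in seq_len(nrow(anchors))) {
    pos <- tx_shift(anchors$center[i], offs, anchors$strand[i])
    acc <- acc + track_counts_at(track, anchors$contig[i],
                                 anchors$strand[i], pos)
  }
  acc
}

#' Crosslink metaprofile around a PAS anchor set
#'
#' Two-step normalization: at each offset in `window[1]..window[2]`
#' (default -400..+100), the crosslink counts of the track are summed
#' over anchors, divided by the number of anchors, then divided by the
#' library's total number of positions with crosslink events. A loess
#' smoothing is added. Duplicating every anchor leaves the profile
#' unchanged.
#'
#' @param track a [crosslink_track].
#' @param anchors data.frame with `contig`, `strand`, `center`.
#' @param window integer length-2 offset window (default `c(-400, 100)`).
#' @param span loess span (default 0.1).
#' @return data.frame `offset`, `raw`, `smooth` of class
#'   `xlink_profile`; attributes `n_anchors` and `n_positions`.
#' @export
pas_metaprofile <- function(track, anchors, window = c(-400L, 100L),
                            span = 0.1) {
  if (!nrow(anchors)) stop("empty anchor set", call. = FALSE)
  if (track$n_positions == 0L) {
    stop("track has no crosslink positions", call. = FALSE)
  }
  offs <- window[1]:window[2]
  raw <- anchor_offset_counts(track, anchors, window) /
    nrow(anchors) / track$n_positions
  out <- data.frame(offset = offs, raw = raw,
                    smooth = loess_smooth(offs, raw, span))
  class(out) <- c("xlink_profile", class(out))
  attr(out, "n_anchors") <- nrow(anchors)
  attr(out, "n_positions") <- track$n_positions
  out
}

#' Compare two crosslink tracks around the same anchors
#'
#' At each offset, `x_a` and `x_b` are the crosslink counts of the two
#' libraries summed over the anchors. Library B is rescaled by the
#' factor `f` = (positions with crosslink events in A) / (positions
#' with crosslink events in B); a pooled two-proportions z-test is then
#' run on `(x_a, n_a)` versus `(x_b * f, n_b * f)` where `n_a`, `n_b`
#' are the libraries' total crosslink events. Two-sided normal P
#' values, Benjamini-Hochberg across offsets, flags at `FDR <= fdr`.
#'
#' @param track_a,track_b [crosslink_track] objects.
#' @param anchors shared anchor set (`contig`, `strand`, `center`).
#' @param window offset window (default `c(-400, 100)`).
#' @param fdr flag threshold (default 0.01).
#' @return list of class `xlink_comparison`: `table` (per-offset `x_a`,
#'   `x_b`, `z`, `p`, `fdr`, `flag`), `scaling_factor`, `n_a`, `n_b`.
#' @export
compare_profiles <- function(track_a, track_b, anchors,
                             window = c(-400L, 100L), fdr = 0.01) {
  if (!nrow(anchors)) stop("empty anchor set", call. = FALSE)
  n_a <- track_a$n_events
  n_b <- track_b$n_events
  if (n_a == 0 || n_b == 0) {
    stop("zero total crosslink events in a library", call. = FALSE)
  }
  f <- track_a$n_positions / track_b$n_positions
  offs <- window[1]:window[2]
  x_a <- anchor_offset_counts(track_a, anchors, window)
  x_b <- anchor_offset_counts(track_b, anchors, window)
  z <- two_proportions_z(x_a, n_a, x_b * f, n_b * f)
  p <- 2 * pnorm(-abs(z))
  q <- bh_adjust(p)
  tab <- data.frame(offset = offs, x_a = x_a, x_b = x_b, z = z,
                    p = p, fdr = q, flag = !is.na(q) & q <= fdr)
  out <- list(table = tab, scaling_factor = f, n_a = n_a, n_b = n_b)
  class(out) <- "xlink_comparison"
  out
}

#' Pooled two-proportions z statistic
#'
#' `z = (x1/n1 - x2/n2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with the
#' pooled proportion `p = (x1 + x2) / (n1 + n2)`; 0 when both
#' proportions are equal (including both 0), NA when the pooled
#' variance is 0 but the proportions differ.
#'
#' @param x1,n1,x2,n2 successes and totals (vectorized).
#' @return numeric z values.
#' @export
two_proportions_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, ifelse(p1 == p2, 0, NA_real_))
  as.numeric(z)
}

#' @export
print.xlink_comparison <- function(x, ...) {
  cat("crosslink comparison over ", nrow(x$table), " offsets: ",
      sum(x$table$flag, na.rm = TRUE), " flagged, scaling factor ",
      format(x$scaling_factor, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Background z-scores for a crosslink metaprofile
#'
#' Identical contract to [motif_background_zscore()] but over
#' normalized crosslink profiles: the target anchors' raw profile is
#' compared per offset against `n_resamples` size-matched anchor sets
#' drawn without replacement from an unaffected pool. Offsets with zero
#' background sd are excluded from the BH correction and reported.
#'
#' @param target_anchors,pool_anchors anchor data.frames; the pool must
#'   be at least as large as the target.
#' @param track a [crosslink_track].
#' @param window offset window (default `c(-400, 100)`).
#' @param n_resamples number of background draws (default 100).
#' @param fdr flag threshold (default 0.01).
#' @param seed integer seed.
#' @return data.frame as in [motif_background_zscore()].
#' @export
profile_background_z <- function(target_anchors, pool_anchors, track,
                                 window = c(-400L, 100L),
                                 n_resamples = 100L, fdr = 0.01,
                                 seed = 1L) {
  n_t <- nrow(target_anchors)
  if (nrow(pool_anchors) < n_t) {
    stop("background pool smaller than target set", call. = FALSE)
  }
  if (track$n_positions == 0L) {
    stop("track has no crosslink positions", call. = FALSE)
  }
  set.seed(seed)
  # each anchor's counts are looked up exactly once; resamples only
  # combine rows
  tgt_raw <- colSums(anchor_count_matrix(track, target_anchors, window)) /
    n_t / track$n_positions
  pool_m <- anchor_count_matrix(track, pool_anchors, window)
  bg <- matrix(0, n_resamples, ncol(pool_m))
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(nrow(pool_anchors), n_t, replace = FALSE)
    bg[r, ] <- colSums(pool_m[idx, , drop = FALSE]) / n_t /
      track$n_positions
  }
  resample_z_core(window[1]:window[2], tgt_raw, bg, fdr)
}

# Per-anchor crosslink count matrix (anchors x offsets).
anchor_count_matrix <- function(track, anchors, win) {
  offs <- win[1]:win[2]
  m <- matrix(0, nrow(anchors), length(offs))
  for (i in seq_len(nrow(anchors))) {
    pos <- tx_shift(anchors$center[i], offs, anchors$strand[i])
    m[i, ] <- track_counts_at(track, anchors$contig[i],
                              anchors$strand[i], pos)
  }
  m
}
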