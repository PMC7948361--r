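# Matched-background resampling z-scores shared by the motif and
# crosslink metaprofile machinery.

# Core: target vector vs a resample matrix (n_resamples x n_offsets).
resample_z_core <- function(offsets, target, bg, fdr = 0.01) {
  mu <- colMeans(bg)
  sdv <- apply(bg, 2, sd)
  z <- rep(NA_real_, length(target))
  ok <- sdv > 0
  z[ok] <- (target[ok] - mu[ok]) / sdv[ok]
  p <- rep(NA_real_, length(target))
  p[ok] <- 2 * pnorm(-abs(z[ok]))
  q <- bh_adjust(p)
  data.frame(offset = offsets, target = target, bg_mean = mu, bg_sd = sdv,
             z = z, p = p, fdr = q,
             flag = !is.na(q) & q <= fdr,
             excluded = !ok)
}

#' Background z-scores for a motif metaprofile
#'
#' Compares the raw motif metaprofile of a target PAS set against the
#' mean and standard deviation of `n_resamples` size-matched sets drawn
#' without replacement from a background pool of unaffected PASs:
#' `z = (target - mean_bg) / sd_bg` per offset, two-sided normal P
#' values, Benjamini-Hochberg correction across offsets, and flags at
#' `FDR <= fdr`. Offsets with zero background sd are excluded from the
#' correction and reported as such.
#'
#' @param target_anchors,pool_anchors data.frames with `contig`,
#'   `strand`, `center`; the pool must be at least as large as the
#'   target.
#' @param genome a `DNAStringSet`.
#' @param pattern IUPAC motif.
#' @param half_window half window in nt.
#' @param n_resamples number of background draws (default 100).
#' @param fdr flag threshold (default 0.01).
#' @param seed integer seed; results are bit-reproducible given a seed.
#' @return data.frame with per-offset `target`, `bg_mean`, `bg_sd`, `z`,
#'   `p`, `fdr`, `flag`, `excluded`.
#' @export
motif_background_zscore <- function(target_anchors, pool_anchors, genome,
                                    pattern, half_window = 300L,
                                    n_resamples = 100L, fdr = 0.01,
                                    seed = 1L) {
  n_t <- nrow(target_anchors)
  if (nrow(pool_anchors) < n_t) {
    stop("background pool smaller than target set", call. = FALSE)
  }
  set.seed(seed)
  # each anchor is scanned exactly once; resamples only average rows
  tgt_raw <- colMeans(motif_hit_matrix(target_anchors, genome, pattern,
                                       half_window))
  pool_m <- motif_hit_matrix(pool_anchors, genome, pattern, half_window)
  bg <- matrix(0, n_resamples, ncol(pool_m))
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(nrow(pool_anchors), n_t, replace = FALSE)
    bg[r, ] <- colMeans(pool_m[idx, , drop = FALSE])
  }
  resample_z_core(-half_window:half_window, tgt_raw, bg, fdr)
}

# Per-anchor motif-presence indicator matrix (anchors x offsets).
motif_hit_matrix <- function(anchors, genome, pattern, half_window) {
  m <- matrix(0, nrow(anchors), 2L * half_window + 1L)
  for (i in seq_len(nrow(anchors))) {
    st <- unique(scan_motif(genome, anchors$contig[i], anchors$strand[i],
                            anchors$center[i], pattern, half_window))
    st <- st[st >= -half_window & st <= half_window]
    if (length(st)) m[i, st + half_window + 1L] <- 1
  }
  m
}
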