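# Permutation-FDR calling of significant crosslink positions within
# genes.

#' Call significant crosslink positions by within-gene permutation
#'
#' Per gene, the gene's total crosslink events are redistributed
#' uniformly over the gene's positions `n_perm` times. For every
#' observed count height `h`, `FDR(h)` is the mean permuted number of
#' positions with count >= `h` divided by the observed number of
#' positions with count >= `h`; a position is significant when the FDR
#' of its own count height is below `fdr`. Genes with fewer than 2
#' events yield no calls; crosslinks outside every gene are ignored.
#'
#' @param track a [crosslink_track].
#' @param models a [gene_models] object.
#' @param n_perm number of permutations (default 100; must be >= 1).
#' @param fdr significance threshold (default 0.05, strict `<`).
#' @param seed integer seed.
#' @return data.frame of considered positions: `contig`, `strand`,
#'   `position`, `count`, `gene_id`, `fdr`, `significant`.
#' @export
call_significant_xlinks <- function(track, models, n_perm = 100L,
                                    fdr = 0.05, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  set.seed(seed)
  genes <- models$genes
  ev <- track$events
  out <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    sel <- ev$contig == g$contig & ev$strand == g$strand &
      ev$position >= g$start & ev$position <= g$end
    gd <- ev[sel, , drop = FALSE]
    if (!nrow(gd)) next
    total <- sum(gd$count)
    len <- g$end - g$start + 1L
    gd$gene_id <- g$gene_id
    if (total < 2L) {
      gd$fdr <- NA_real_
      gd$significant <- FALSE
      out[[length(out) + 1L]] <- gd
      next
    }
    heights <- sort(unique(gd$count))
    obs_ge <- vapply(heights, function(h) sum(gd$count >= h), numeric(1))
    perm_ge <- matrix(0, n_perm, length(heights))
    for (r in seq_len(n_perm)) {
      cnt <- tabulate(sample.int(len, total, replace = TRUE), nbins = len)
      cnt <- cnt[cnt > 0L]
      perm_ge[r, ] <- vapply(heights, function(h) sum(cnt >= h),
                             numeric(1))
    }
    fdr_h <- pmin(colMeans(perm_ge) / obs_ge, 1)
    gd$fdr <- fdr_h[match(gd$count, heights)]
    gd$significant <- gd$fdr < fdr
    out[[length(out) + 1L]] <- gd
  }
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      position = integer(), count = integer(),
                      gene_id = character(), fdr = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
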