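# k-mer enrichment around significant crosslink positions versus
# within-gene shuffled controls.

# Count k-mer starts in the two flank intervals of one site (tx offsets
# -30..-5 and +5..+30, clipped to the gene span and contig). Returns a
# named integer vector of counts plus the number of k-mer windows
# scanned in attr "n_windows".
flank_kmer_counts <- function(genome, contig, strand, position,
                              gene_start, gene_end, k) {
  counts <- integer(0)
  n_win <- 0L
  for (iv in list(c(-30L, -5L), c(5L, 30L))) {
    if (strand == "+") {
      lo <- position + iv[1]; hi <- position + iv[2]
    } else {
      lo <- position - iv[2]; hi <- position - iv[1]
    }
    lo <- max(lo, gene_start); hi <- min(hi, gene_end)
    if (hi - lo + 1L < k) next
    s <- extract_tx_seq(genome, contig, strand, lo, hi)$seq
    n <- nchar(s)
    if (n < k) next
    for (j in seq_len(n - k + 1L)) {
      km <- substr(s, j, j + k - 1L)
      counts[km] <- if (km %in% names(counts)) counts[[km]] + 1L else 1L
      n_win <- n_win + 1L
    }
  }
  attr(counts, "n_windows") <- n_win
  counts
}

# Sum flank k-mer counts over a set of sites.
sites_kmer_counts <- function(sites, genome, gene_lut, k) {
  acc <- integer(0)
  total <- 0L
  for (i in seq_len(nrow(sites))) {
    g <- gene_lut[[sites$gene_id[i]]]
    cnt <- flank_kmer_counts(genome, sites$contig[i], sites$strand[i],
                             sites$position[i], g[1], g[2], k)
    total <- total + attr(cnt, "n_windows")
    for (km in names(cnt)) {
      acc[km] <- if (km %in% names(acc)) acc[[km]] + cnt[[km]] else cnt[[km]]
    }
  }
  attr(acc, "n_windows") <- total
  acc
}

#' k-mer z-scores around significant crosslink positions
#'
#' Counts every k-mer occurrence in the two flank intervals (-30..-5
#' and +5..+30 nt in transcription direction, the crosslink-proximal
#' -4..+4 nt excluded; flanks are clipped at gene edges) around each
#' significant crosslink, then relocates the significant positions
#' `n_shuffles` times uniformly within their genes and recounts. The
#' per-k-mer z-score is `(observed - shuffle_mean) / shuffle_sd`
#' (undefined when the shuffle sd is 0); k-mers are ranked by
#' decreasing z.
#'
#' @param sites data.frame of significant crosslinks with `contig`,
#'   `strand`, `position`, `gene_id` (see [call_significant_xlinks()]).
#' @param genome a `DNAStringSet`.
#' @param models a [gene_models] object.
#' @param k k-mer length (default 5).
#' @param n_shuffles number of within-gene shuffles (default 100).
#' @param seed integer seed.
#' @return data.frame `kmer`, `observed`, `shuffle_mean`, `shuffle_sd`,
#'   `z`, `rank`, sorted by rank; `attr(, "n_windows")` holds the total
#'   number of k-mer windows scanned (equal to the sum of the observed
#'   counts).
#' @export
kmer_zscore <- function(sites, genome, models, k = 5L,
                        n_shuffles = 100L, seed = 1L) {
  if (!nrow(sites)) stop("significant set is empty", call. = FALSE)
  set.seed(seed)
  genes <- models$genes
  gene_lut <- stats::setNames(
    lapply(seq_len(nrow(genes)),
           function(i) c(genes$start[i], genes$end[i])),
    genes$gene_id)

  obs <- sites_kmer_counts(sites, genome, gene_lut, k)
  kmers <- sort(names(obs))
  shuf <- matrix(0, n_shuffles, length(kmers),
                 dimnames = list(NULL, kmers))
  extra <- list()
  for (r in seq_len(n_shuffles)) {
    moved <- sites
    for (i in seq_len(nrow(moved))) {
      g <- gene_lut[[moved$gene_id[i]]]
      moved$position[i] <- g[1] - 1L + sample.int(g[2] - g[1] + 1L, 1L)
    }
    cnt <- sites_kmer_counts(moved, genome, gene_lut, k)
    new <- setdiff(names(cnt), colnames(shuf))
    if (length(new)) {
      shuf <- cbind(shuf, matrix(0, n_shuffles, length(new),
                                 dimnames = list(NULL, new)))
    }
    shuf[r, names(cnt)] <- cnt
  }
  kmers <- colnames(shuf)
  observed <- as.integer(obs[kmers])
  observed[is.na(observed)] <- 0L
  mu <- colMeans(shuf)
  sdv <- apply(shuf, 2, sd)
  z <- ifelse(sdv > 0, (observed - mu) / sdv, NA_real_)
  ord <- order(-z, kmers, na.last = TRUE)
  out <- data.frame(kmer = kmers[ord], observed = observed[ord],
                    shuffle_mean = mu[ord], shuffle_sd = sdv[ord],
                    z = z[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_windows") <- attr(obs, "n_windows")
  out
}
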