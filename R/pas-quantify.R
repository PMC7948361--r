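# Quantification (CE / PU / TPM) and filtering of 15-nt PAS windows.

#' Quantify PAS windows per sample and apply the atlas filter
#'
#' Cleavage events of each sample are recounted into every 15-nt window
#' (`CE`); within each condition replicates are averaged
#' (`CE_average`). Percent usage (`PU`) divides a window's CE by all
#' cleavage events of the complete gene (gene span extended 50 nt
#' downstream, where PASs can still be assigned) times 100. The
#' depth-normalized `TPM` is `CE / 0.015 / (library_size / 1e6)` with
#' the library size of a sample taken as its total (trimmed,
#' deduplicated, artifact-filtered) cleavage events; `TPM_maximum` is
#' the per-gene maximum of `TPM_average` over the gene's windows. A
#' window is retained iff, taking the maximum across conditions,
#' `CE_average > min_ce` AND `PU_average > min_pu` AND the gene-level
#' `TPM_maximum > min_tpm` (all comparisons strict, the defaults being
#' 4 events, 5 percent and 0.25).
#'
#' @param windows PAS windows with a `gene_id` column (see
#'   [assign_gene_and_region()]).
#' @param events per-sample cleavage events (post artifact filter).
#' @param samples data.frame `sample_id`, `condition`.
#' @param models [gene_models] (for gene extents).
#' @param min_ce,min_pu,min_tpm filter thresholds.
#' @param lib_sizes optional named vector of per-sample library sizes;
#'   defaults to the per-sample event totals.
#' @return list with `windows` (retained rows with per-condition
#'   metrics), `table` (all windows, `pass` flag) and `dropped_genes`
#'   (genes with zero events, skipped with a warning).
#' @export
quantify_and_filter <- function(windows, events, samples, models,
                                min_ce = 4, min_pu = 5, min_tpm = 0.25,
                                lib_sizes = NULL) {
  stopifnot("gene_id" %in% names(windows))
  sids <- samples$sample_id
  conds <- unique(samples$condition)
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(sids, function(s) {
      sum(events$count[events$sample_id == s])
    }, numeric(1))
    names(lib_sizes) <- sids
  }

  genes <- models$genes
  gi <- match(windows$gene_id, genes$gene_id)
  ext_start <- ifelse(genes$strand[gi] == "+", genes$start[gi],
                      genes$start[gi] - 50L)
  ext_end <- ifelse(genes$strand[gi] == "+", genes$end[gi] + 50L,
                    genes$end[gi])

  n_w <- nrow(windows)
  CE <- matrix(0, n_w, length(sids), dimnames = list(NULL, sids))
  gene_tot <- matrix(0, n_w, length(sids), dimnames = list(NULL, sids))
  for (s in sids) {
    ev <- events[events$sample_id == s, , drop = FALSE]
    for (i in seq_len(n_w)) {
      same <- ev$contig == windows$contig[i] &
        ev$strand == windows$strand[i]
      CE[i, s] <- sum(ev$count[same & ev$position >= windows$start[i] &
                                 ev$position <= windows$end[i]])
      gene_tot[i, s] <- sum(ev$count[same & ev$position >= ext_start[i] &
                                       ev$position <= ext_end[i]])
    }
  }

  tab <- windows
  for (cd in conds) {
    reps <- sids[samples$condition == cd]
    ce_avg <- rowMeans(CE[, reps, drop = FALSE])
    pu <- CE[, reps, drop = FALSE] /
      gene_tot[, reps, drop = FALSE] * 100
    pu_avg <- rowMeans(pu, na.rm = TRUE)
    pu_avg[!is.finite(pu_avg)] <- NA_real_
    tpm <- sweep(CE[, reps, drop = FALSE], 2,
                 lib_sizes[reps] / 1e6, "/") / 0.015
    tpm_avg <- rowMeans(tpm)
    tpm_max <- stats::ave(tpm_avg, windows$gene_id, FUN = max)
    tab[[paste0("CE_average.", cd)]] <- ce_avg
    tab[[paste0("PU_average.", cd)]] <- pu_avg
    tab[[paste0("TPM_average.", cd)]] <- tpm_avg
    tab[[paste0("TPM_maximum.", cd)]] <- tpm_max
  }

  zero_gene <- rowSums(gene_tot) == 0
  dropped_genes <- unique(windows$gene_id[zero_gene])
  if (length(dropped_genes)) {
    warning("skipping windows of ", length(dropped_genes),
            " gene(s) with zero cleavage events", call. = FALSE)
  }

  max_over <- function(prefix) {
    m <- as.matrix(tab[paste0(prefix, ".", conds)])
    apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  }
  pass <- !zero_gene &
    max_over("CE_average") > min_ce &
    max_over("PU_average") > min_pu &
    max_over("TPM_maximum") > min_tpm
  pass[is.na(pass)] <- FALSE
  tab$pass <- pass
  list(windows = tab[pass, , drop = FALSE], table = tab,
       dropped_genes = dropped_genes)
}
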