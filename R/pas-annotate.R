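# Gene / region assignment, s-p-o-d typing and CSE annotation of PAS
# windows.

#' Assign PAS windows to genes and transcript regions
#'
#' A window is assigned by the overlap of its center with gene spans on
#' the same strand. Centers overlapping more than one gene are removed.
#' Centers in no gene but 1-50 nt downstream (transcription direction)
#' of exactly one gene are assigned to that gene's 3'UTR; all other
#' unassigned centers are removed and counted. The region of an
#' assigned center follows the overlap with the gene's 5'UTR / CDS /
#' intron / 3'UTR regions; overlaps including a 3'UTR are called
#' "3UTR", overlaps including an intron (but no 3'UTR) "intron", other
#' multi-region or unannotated overlaps "Other".
#'
#' @param windows PAS windows (from [define_pas_windows()]).
#' @param models a [gene_models] object.
#' @param downstream_nt how far downstream of a gene end a center may
#'   still be claimed (default 50).
#' @return list with `windows` (assigned rows plus `gene_id`, `region`,
#'   `distance_to_annotated_end`), `n_removed_multi` and
#'   `n_removed_unassigned`.
#' @export
assign_gene_and_region <- function(windows, models, downstream_nt = 50L) {
  genes <- models$genes
  gene_gr <- GenomicRanges::GRanges(genes$contig,
                                    IRanges::IRanges(genes$start, genes$end),
                                    strand = genes$strand)
  cen_gr <- GenomicRanges::GRanges(windows$contig,
                                   IRanges::IRanges(windows$center, width = 1L),
                                   strand = windows$strand)
  ov <- GenomicRanges::findOverlaps(cen_gr, gene_gr)
  nhit <- tabulate(S4Vectors::queryHits(ov), nbins = nrow(windows))

  gene_id <- rep(NA_character_, nrow(windows))
  one <- which(nhit == 1L)
  gene_id[one] <- genes$gene_id[S4Vectors::subjectHits(ov)[
    match(one, S4Vectors::queryHits(ov))]]
  multi <- nhit > 1L

  # downstream rule for centers hitting no gene
  down_gr <- GenomicRanges::flank(gene_gr, downstream_nt, start = FALSE)
  none <- which(nhit == 0L)
  region_forced <- rep(NA_character_, nrow(windows))
  if (length(none)) {
    ov2 <- GenomicRanges::findOverlaps(cen_gr[none], down_gr)
    nhit2 <- tabulate(S4Vectors::queryHits(ov2), nbins = length(none))
    ok <- which(nhit2 == 1L)
    gene_id[none[ok]] <- genes$gene_id[S4Vectors::subjectHits(ov2)[
      match(ok, S4Vectors::queryHits(ov2))]]
    region_forced[none[ok]] <- "3UTR"
    multi[none[nhit2 > 1L]] <- TRUE
  }

  keep <- !is.na(gene_id)
  n_removed_multi <- sum(multi)
  n_removed_unassigned <- sum(!keep & !multi)

  out <- windows[keep, , drop = FALSE]
  out$gene_id <- gene_id[keep]
  forced <- region_forced[keep]

  # region by overlap with the assigned gene's regions
  reg <- models$regions
  region <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!is.na(forced[i])) {
      region[i] <- forced[i]
      next
    }
    r <- reg[reg$gene_id == out$gene_id[i], , drop = FALSE]
    hit <- unique(r$kind[r$start <= out$center[i] & out$center[i] <= r$end])
    region[i] <- if ("3UTR" %in% hit) "3UTR"
    else if ("intron" %in% hit) "intron"
    else if (length(hit) == 1L) hit
    else "Other"
  }
  out$region <- region

  gi <- match(out$gene_id, genes$gene_id)
  g3p <- ifelse(genes$strand[gi] == "+", genes$end[gi], genes$start[gi])
  out$distance_to_annotated_end <- tx_offset(out$center, g3p,
                                             genes$strand[gi])
  rownames(out) <- NULL
  list(windows = out, n_removed_multi = n_removed_multi,
       n_removed_unassigned = n_removed_unassigned)
}

#' Type PASs as sPAS / pPAS / oPAS / dPAS within each gene
#'
#' Per gene (in transcription direction) the most upstream PAS is the
#' proximal pPAS, the most downstream the distal dPAS, anything in
#' between an oPAS; a gene's only PAS is its single sPAS.
#'
#' @param records assigned PAS windows (with `gene_id`).
#' @return `records` with a `pas_type` column.
#' @export
classify_pas_types <- function(records) {
  records$pas_type <- NA_character_
  for (gid in unique(records$gene_id)) {
    i <- which(records$gene_id == gid)
    if (length(i) == 1L) {
      records$pas_type[i] <- "sPAS"
    } else {
      o <- i[tx_order(records$center[i], records$strand[i])]
      records$pas_type[o] <- c("pPAS", rep("oPAS", length(i) - 2L), "dPAS")
    }
  }
  records
}

#' Assign a CSE hexamer to each PAS by hierarchy
#'
#' Searches the 50 nt upstream (transcription direction, strand-aware)
#' of each PAS cleavage site for start positions of the configured
#' hexamers (the hexamer must lie fully inside the window). AAUAAA wins
#' over everything, then AUUAAA, then the remaining hexamer whose start
#' lies closest to the PAS (ties broken alphabetically). `NA` when no
#' listed hexamer occurs. Windows truncated by a contig edge are
#' searched in their available part and flagged.
#'
#' @param records assigned PAS windows.
#' @param genome a `DNAStringSet`.
#' @param hexamers hexamer table from [cse_hexamers()].
#' @param window_nt upstream search window (default 50).
#' @return `records` with `cse` (RNA hexamer or NA), `cse_offset`
#'   (tx offset of the hexamer start relative to the cleavage site) and
#'   `cse_truncated` columns.
#' @export
assign_cse <- function(records, genome, hexamers = cse_hexamers(),
                       window_nt = 50L) {
  n <- nrow(records)
  cse <- rep(NA_character_, n)
  cse_off <- rep(NA_integer_, n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    center <- records$center[i]
    strand <- records$strand[i]
    lo <- if (strand == "+") center - window_nt else center + 1L
    hi <- if (strand == "+") center - 1L else center + window_nt
    w <- extract_tx_seq(genome, records$contig[i], strand, lo, hi)
    trunc[i] <- w$truncated
    wlen <- nchar(w$seq)
    if (wlen < 6L) next
    hits <- list()
    for (k in seq_len(nrow(hexamers))) {
      st <- gregexpr(hexamers$dna[k], w$seq, fixed = TRUE)[[1]]
      st <- st[st > 0]
      if (length(st)) {
        hits[[hexamers$hexamer[k]]] <- st
      }
    }
    if (!length(hits)) next
    # tx offset of window index j: j - wlen - 1 (window ends 1 nt
    # upstream of the cleavage site)
    to_off <- function(j) as.integer(j - wlen - 1L)
    if ("AAUAAA" %in% names(hits)) {
      cse[i] <- "AAUAAA"
      cse_off[i] <- to_off(max(hits[["AAUAAA"]]))
    } else if ("AUUAAA" %in% names(hits)) {
      cse[i] <- "AUUAAA"
      cse_off[i] <- to_off(max(hits[["AUUAAA"]]))
    } else {
      best <- vapply(hits, max, numeric(1))
      top <- names(best)[best == max(best)]
      pickn <- sort(top)[1]
      cse[i] <- pickn
      cse_off[i] <- to_off(max(hits[[pickn]]))
    }
  }
  records$cse <- cse
  records$cse_offset <- cse_off
  records$cse_truncated <- trunc
  records
}
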