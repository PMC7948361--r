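# Integration of external APA-caller (DaPars-style) tables with the
# MACE-derived PAS atlas.

#' Match external APA-caller PASs to atlas PASs
#'
#' An external PAS matches an atlas PAS of the same gene and the same
#' type (pPAS-pPAS or dPAS-dPAS) when it lies at most `up_nt` upstream
#' or `down_nt` downstream (transcription direction) of the atlas
#' cleavage site. When several candidates match, the closer one (by
#' absolute distance) wins; each external PAS is matched at most once.
#'
#' @param dapars data.frame from [read_dapars_table()] (with `ppas` and
#'   `dpas` coordinates).
#' @param records typed atlas PASs (with `gene_id`, `pas_type`,
#'   `center`, `strand`).
#' @param up_nt,down_nt matching window in nt (defaults 250 / 50).
#' @return data.frame of matched pairs: `gene_id`, `pas_type`,
#'   `mace_center`, `dapars_pos`, `distance` (tx-signed, negative =
#'   external PAS upstream of the atlas PAS).
#' @export
match_dapars <- function(dapars, records, up_nt = 250L, down_nt = 50L) {
  long <- rbind(
    data.frame(gene_id = dapars$gene_id, pas_type = "pPAS",
               pos = dapars$ppas, stringsAsFactors = FALSE),
    data.frame(gene_id = dapars$gene_id, pas_type = "dPAS",
               pos = dapars$dpas, stringsAsFactors = FALSE))
  long <- long[!is.na(long$pos), , drop = FALSE]
  rec <- records[records$pas_type %in% c("pPAS", "dPAS"), , drop = FALSE]

  cand <- list()
  for (i in seq_len(nrow(rec))) {
    di <- which(long$gene_id == rec$gene_id[i] &
                  long$pas_type == rec$pas_type[i])
    if (!length(di)) next
    rel <- tx_offset(long$pos[di], rec$center[i], rec$strand[i])
    ok <- rel >= -up_nt & rel <= down_nt
    if (!any(ok)) next
    cand[[length(cand) + 1L]] <- data.frame(
      mace_i = i, dapars_i = di[ok], distance = rel[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) {
    return(data.frame(gene_id = character(), pas_type = character(),
                      mace_center = integer(), dapars_pos = integer(),
                      distance = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$distance)), , drop = FALSE]
  used_m <- logical(nrow(rec)); used_d <- logical(nrow(long))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    m <- cand$mace_i[k]; d <- cand$dapars_i[k]
    if (!used_m[m] && !used_d[d]) {
      keep[k] <- TRUE
      used_m[m] <- TRUE; used_d[d] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(gene_id = rec$gene_id[cand$mace_i],
             pas_type = rec$pas_type[cand$mace_i],
             mace_center = rec$center[cand$mace_i],
             dapars_pos = long$pos[cand$dapars_i],
             distance = cand$distance,
             stringsAsFactors = FALSE)
}

#' Threshold an APA table into shortened / lengthened gene sets
#'
#' Significant 3'UTR shortening: `fdr <= fdr_max` and
#' `delta_pdui <= -min_abs_dpdui`; lengthening: `fdr <= fdr_max` and
#' `delta_pdui >= min_abs_dpdui` (boundaries inclusive). The two sets
#' are disjoint.
#'
#' @param dapars data.frame from [read_dapars_table()].
#' @param fdr_max FDR threshold (default 0.1).
#' @param min_abs_dpdui minimum |delta PDUI| (default 0.05).
#' @return list with character vectors `shortened` and `lengthened`.
#' @export
threshold_apa <- function(dapars, fdr_max = 0.1, min_abs_dpdui = 0.05) {
  sig <- dapars$fdr <= fdr_max
  list(
    shortened = dapars$gene_id[sig & dapars$delta_pdui <= -min_abs_dpdui],
    lengthened = dapars$gene_id[sig & dapars$delta_pdui >= min_abs_dpdui])
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' @param set_a,set_b character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe character vector of all eligible genes.
#' @return list with `overlap`, `odds_ratio` and two-sided `p_value`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(intersect(set_a, universe))
  set_b <- unique(intersect(set_b, universe))
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "two.sided")
  list(overlap = tab[1, 1], odds_ratio = unname(ft$estimate),
       p_value = ft$p.value)
}
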