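# Column aliases accepted for tables produced by DaPars-style APA
# callers. The canonical (package) names win on conflict.
DAPARS_ALIASES <- list(
  gene_id = c("gene_id", "Gene"),
  ppas = c("ppas", "Predicted_Proximal_APA"),
  dpas = c("dpas", "Annotated_Distal_APA"),
  pdui_control = c("pdui_control", "PDUI_Group_A", "A_PDUI"),
  pdui_condition = c("pdui_condition", "PDUI_Group_B", "B_PDUI"),
  fdr = c("fdr", "adjusted.P_val", "adjusted_P_val", "FDR")
)

#' Read an APA result table (DaPars dialect)
#'
#' Reads a TSV of per-gene percentage-of-distal-usage-index (PDUI) values
#' from an external APA caller. Both the caller's native column names and
#' the canonical names (`gene_id`, `ppas`, `dpas`, `pdui_control`,
#' `pdui_condition`, `fdr`) are accepted; canonical names win when both
#' are present. `delta_pdui` is always recomputed as
#' `pdui_condition - pdui_control`. Rows with a missing FDR are dropped
#' (count reported via a message); rows with a PDUI outside \[0, 1\] are
#' rejected with a warning.
#'
#' @param path path to a tab-separated table with a header line.
#' @return data.frame with columns `gene_id`, `ppas`, `dpas`,
#'   `pdui_control`, `pdui_condition`, `delta_pdui`, `fdr`. `ppas`/`dpas`
#'   are NA when the input table does not carry coordinates.
#' @export
read_dapars_table <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(field) {
    for (nm in DAPARS_ALIASES[[field]]) {
      if (nm %in% names(raw)) return(raw[[nm]])
    }
    NULL
  }
  gene_id <- pick("gene_id")
  pc <- pick("pdui_control")
  pk <- pick("pdui_condition")
  fdr <- pick("fdr")
  if (is.null(gene_id) || is.null(pc) || is.null(pk) || is.null(fdr)) {
    stop("DaPars table must carry gene, two PDUI columns and an FDR",
         call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    ppas = as.integer(pick("ppas") %||% rep(NA_integer_, nrow(raw))),
    dpas = as.integer(pick("dpas") %||% rep(NA_integer_, nrow(raw))),
    pdui_control = as.numeric(pc),
    pdui_condition = as.numeric(pk),
    fdr = as.numeric(fdr),
    stringsAsFactors = FALSE)

  n_nafdr <- sum(is.na(out$fdr))
  if (n_nafdr) {
    message("read_dapars_table: dropped ", n_nafdr, " row(s) with missing FDR")
    out <- out[!is.na(out$fdr), , drop = FALSE]
  }
  bad <- is.na(out$pdui_control) | is.na(out$pdui_condition) |
    out$pdui_control < 0 | out$pdui_control > 1 |
    out$pdui_condition < 0 | out$pdui_condition > 1
  if (any(bad)) {
    warning("read_dapars_table: rejected ", sum(bad),
            " row(s) with PDUI outside [0,1]", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$delta_pdui <- out$pdui_condition - out$pdui_control
  rownames(out) <- NULL
  out[, c("gene_id", "ppas", "dpas", "pdui_control", "pdui_condition",
          "delta_pdui", "fdr")]
}
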