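# Motif scanning and metaprofiles around PAS anchors. RNA motifs
# (e.g. UGUA) are matched as DNA on the coding strand; IUPAC degeneracy
# is honoured.

#' Scan a motif around one PAS anchor
#'
#' Extracts the transcript-oriented sequence from `half_window` nt
#' upstream to `half_window` nt downstream of the cleavage site
#' (strand-aware; truncated windows at contig edges are scanned in
#' their available part) and reports all motif start offsets relative
#' to the cleavage site (offset 0 = cleavage site, negative =
#' upstream). Overlapping matches are all reported.
#'
#' @param genome a `DNAStringSet`.
#' @param contig,strand,center anchor coordinates.
#' @param pattern motif in RNA or DNA alphabet, IUPAC codes allowed
#'   (e.g. "UGUA", "CNYC", "GAY").
#' @param half_window half window in nt (default 300).
#' @return integer vector of start offsets (possibly empty).
#' @export
scan_motif <- function(genome, contig, strand, center, pattern,
                       half_window = 300L) {
  w <- extract_tx_seq(genome, contig, strand,
                      center - half_window, center + half_window)
  if (!nchar(w$seq)) return(integer(0))
  pat <- rna_to_dna(pattern)
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(w$seq),
                                fixed = FALSE)
  if (!length(m)) return(integer(0))
  st <- Biostrings::start(m)
  # tx offset of window index 1
  first_off <- if (strand == "+") w$lo - center else center - w$hi
  as.integer(first_off + st - 1L)
}

#' Motif metaprofile around a PAS anchor set
#'
#' For every offset in `-half_window .. +half_window`, the raw profile
#' is the fraction of anchors that carry at least one motif start at
#' that offset; a loess smoothing (local quadratic regression, span
#' `span`) is added. Duplicated anchors do not change the profile.
#'
#' @param anchors data.frame with `contig`, `strand`, `center`.
#' @param genome a `DNAStringSet`.
#' @param pattern IUPAC motif (RNA or DNA alphabet).
#' @param half_window half window in nt (default 300).
#' @param span loess span as a fraction of the window (default 0.1).
#' @return data.frame `offset`, `raw`, `smooth` of class
#'   `motif_profile`; `attr(, "n_anchors")` carries the anchor count.
#' @export
motif_metaprofile <- function(anchors, genome, pattern,
                              half_window = 300L, span = 0.1) {
  if (!nrow(anchors)) stop("need at least one anchor", call. = FALSE)
  offs <- -half_window:half_window
  acc <- numeric(length(offs))
  for (i in seq_len(nrow(anchors))) {
    st <- unique(scan_motif(genome, anchors$contig[i], anchors$strand[i],
                            anchors$center[i], pattern, half_window))
    st <- st[st >= -half_window & st <= half_window]
    if (length(st)) {
      acc[st + half_window + 1L] <- acc[st + half_window + 1L] + 1
    }
  }
  raw <- acc / nrow(anchors)
  out <- data.frame(offset = offs, raw = raw,
                    smooth = loess_smooth(offs, raw, span))
  class(out) <- c("motif_profile", class(out))
  attr(out, "n_anchors") <- nrow(anchors)
  out
}

# Loess smoothing used for all profiles (degree-2 local regression).
loess_smooth <- function(x, y, span = 0.1) {
  fit <- loess(y ~ x, span = span, degree = 2,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  as.numeric(predict(fit, x))
}
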