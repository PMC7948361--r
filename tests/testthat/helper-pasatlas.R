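# Shared fixtures and independent oracles for the test suite. All
# fixtures are generated in code; nothing binary is read from disk.

toy_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# A deliberately simple two-gene model set on one contig.
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    contig = "chr1",
    strand = c("+", "-"),
    start = c(101L, 1001L),
    end = c(600L, 1500L),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB"),
    kind = c("5UTR", "CDS", "intron", "3UTR", "3UTR", "CDS", "5UTR"),
    start = c(101L, 151L, 301L, 401L, 1001L, 1201L, 1401L),
    end = c(150L, 300L, 400L, 600L, 1200L, 1400L, 1500L),
    stringsAsFactors = FALSE)
  gene_models(genes, regions)
}

# --- independent clustering oracle -----------------------------------
# Literal transcription of the rule: process positions in transcription
# order; admit the next position if its distance to the current running
# median (with multiplicity, even size -> mean of central pair) is
# <= max_dist.
oracle_median <- function(pos, cnt) {
  v <- rep(pos, cnt)
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

oracle_cluster <- function(pos, cnt, strand, max_dist = 25) {
  o <- if (strand == "+") order(pos) else order(-pos)
  pos <- pos[o]; cnt <- cnt[o]
  ids <- integer(length(pos))
  cl <- 0L
  mp <- integer(0); mc <- integer(0)
  for (i in seq_along(pos)) {
    if (length(mp) == 0 ||
        abs(pos[i] - oracle_median(mp, mc)) > max_dist) {
      cl <- cl + 1L
      mp <- pos[i]; mc <- cnt[i]
    } else {
      mp <- c(mp, pos[i]); mc <- c(mc, cnt[i])
    }
    ids[i] <- cl
  }
  ids
}

# --- brute-force CSE oracle ------------------------------------------
# Regex scan of the tx-oriented 50-nt upstream window with explicit
# hierarchy.
oracle_cse <- function(window_seq, hex) {
  starts <- lapply(hex$dna, function(h) {
    s <- gregexpr(h, window_seq, fixed = TRUE)[[1]]
    s[s > 0 & s + 5 <= nchar(window_seq)]
  })
  names(starts) <- hex$hexamer
  has <- vapply(starts, function(s) length(s) > 0, logical(1))
  if (!any(has)) return(NA_character_)
  if (has["AAUAAA"]) return("AAUAAA")
  if (has["AUUAAA"]) return("AUUAAA")
  cand <- names(starts)[has]
  best <- vapply(cand, function(n) max(starts[[n]]), numeric(1))
  sort(cand[best == max(best)])[1]
}

# --- brute-force tandem-UGUA oracle ----------------------------------
# For one anchor: all-pairs check of the mode ranges at every Win_size.
oracle_tandem_qualifies <- function(starts, mode, W) {
  starts <- sort(unique(starts))
  if (length(starts) < 2) return(FALSE)
  for (a in seq_len(length(starts) - 1)) {
    for (b in (a + 1):length(starts)) {
      s1 <- starts[a]; s2 <- starts[b]
      ok <- switch(mode,
        enclosing = s1 >= -W && s1 <= -4 && s2 >= -3 && s2 <= W - 3,
        preceded = s1 >= -W && s2 <= -4,
        followed = s1 >= 1 && s2 <= W - 3)
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# --- closed-form pooled two-proportions z ----------------------------
oracle_two_prop_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# random DNA string
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
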