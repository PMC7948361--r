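# Synthetic genome / annotation / truth-set generator.
#
# The generator emulates the data a 3' end sequencing study starts from:
# multi-gene contigs on both strands, annotated 5'UTR/CDS/intron/3'UTR
# regions, 1-4 true PASs per gene with planted CSE hexamers and UGUA
# motifs, and genomic A-stretches that will later seed internal-priming
# artifact reads. Sequence immediately around each true cleavage site is
# kept A-free and the 50-nt CSE search window is kept free of unplanted
# hexamers, so planted ground truth is unambiguous.

# Write a transcript-sense sequence at tx offset `offset` relative to
# `pas` into the contig character vector (genomic coordinates).
plant_at_tx <- function(chars, strand, pas, offset, seq_tx) {
  L <- nchar(seq_tx)
  if (strand == "+") {
    lo <- pas + offset
    chars[lo:(lo + L - 1L)] <- strsplit(seq_tx, "")[[1]]
  } else {
    lo <- pas - (offset + L - 1L)
    chars[lo:(lo + L - 1L)] <- strsplit(revcomp(seq_tx), "")[[1]]
  }
  chars
}

# Genomic positions of tx offsets lo..hi relative to pas.
tx_window_coords <- function(strand, pas, lo, hi) {
  if (strand == "+") (pas + lo):(pas + hi) else (pas - lo):(pas - hi)
}

#' Simulate a toy genome with annotated genes and known true PASs
#'
#' Generates a random multi-gene genome on both strands. Each gene has a
#' 5'UTR, two CDS segments separated by one intron, and a 3'UTR hosting
#' 1-4 true PASs (count drawn from `pas_count_probs`, matching the
#' roughly 55/27/11/7 percent split observed in mammalian PAS atlases).
#' Every true PAS receives a CSE hexamer drawn from `hexamers$freq`
#' placed with its start 14-32 nt upstream of the cleavage site, plus the
#' motifs in `motif_plant`. Per-PAS usage weights are at least 0.15 and
#' sum to 1 within a gene. `a_stretch_rate` pure-A stretches (12-15 nt,
#' transcript sense) are planted per gene: one inside the 3'UTR (seeding
#' internal-priming artifacts) and the rest in intergenic space.
#'
#' To keep the planted truth unambiguous, accidental occurrences of
#' listed hexamers in each CSE search window are mutated away, and the
#' +/-8 nt around each cleavage site is kept free of transcript-sense
#' adenosines (so poly(A)-tail trimming cannot absorb templated bases).
#'
#' @param n_genes number of genes (>= 1).
#' @param strand_mix fraction of genes on the "-" strand.
#' @param utr_length_range length range of the 3'UTR in nt.
#' @param a_stretch_rate planted A-stretches per gene (0 = none).
#' @param pas_count_probs probabilities for 1, 2, 3, 4 PASs per gene.
#' @param downstream_pas_prob probability that a gene's most distal PAS
#'   lies 1-50 nt downstream of the annotated gene end.
#' @param motif_plant named integer vector of concrete RNA motifs to
#'   plant at fixed tx offsets relative to each PAS (default one UGUA
#'   starting 50 nt upstream).
#' @param hexamers hexamer table from [cse_hexamers()].
#' @param xlink_peak_offset,xlink_peak_sd shape of the per-PAS crosslink
#'   enrichment profile stored in the truth set (a Gaussian bump,
#'   default centered 75 nt upstream).
#' @param seed integer seed; identical seed + configuration give
#'   byte-identical output.
#' @return list with `genome` (DNAStringSet), `models` ([gene_models]),
#'   `truth` (a `truth_set`: `$pas`, `$motifs`, `$a_stretches`,
#'   `$xlink_profile`) and `config`.
#' @export
simulate_genome <- function(n_genes = 20,
                            strand_mix = 0.5,
                            utr_length_range = c(300, 600),
                            a_stretch_rate = 2,
                            pas_count_probs = c(0.55, 0.27, 0.11, 0.07),
                            downstream_pas_prob = 0.1,
                            motif_plant = c(UGUA = -50L),
                            hexamers = cse_hexamers(),
                            xlink_peak_offset = -75L,
                            xlink_peak_sd = 4,
                            seed = 1L) {
  stopifnot(n_genes >= 1, utr_length_range[1] >= 150)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pad <- 200L

  genes <- list(); regions <- list(); pas_rows <- list()
  motif_rows <- list(); stretch_rows <- list()
  chars <- character(0)
  cursor <- 0L

  for (k in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", k)
    strand <- if (runif(1) < strand_mix) "-" else "+"
    utr5 <- sample(60:120, 1)
    cds1 <- sample(150:300, 1)
    intr <- sample(100:200, 1)
    cds2 <- sample(150:300, 1)
    utr3 <- sample(utr_length_range[1]:utr_length_range[2], 1)
    blk <- utr5 + cds1 + intr + cds2 + utr3

    # trailing pad: a downstream PAS may sit up to 50 nt past g_end and
    # its A-free window extends 8 nt further, so allocate 60 nt beyond
    # the gene block before the next gene starts
    tail_pad <- 60L
    chars <- c(chars, sample(bases, pad + blk + tail_pad, replace = TRUE))
    g_start <- cursor + pad + 1L
    g_end <- cursor + pad + blk
    cursor <- cursor + pad + blk + tail_pad

    # region genomic coordinates (tx order 5UTR,CDS,intron,CDS,3UTR)
    lens <- c(utr5, cds1, intr, cds2, utr3)
    kinds <- c("5UTR", "CDS", "intron", "CDS", "3UTR")
    if (strand == "+") {
      ends <- g_start - 1L + cumsum(lens)
      starts <- c(g_start, head(ends, -1) + 1L)
    } else {
      lens_r <- rev(lens)
      ends <- g_start - 1L + cumsum(lens_r)
      starts <- c(g_start, head(ends, -1) + 1L)
      starts <- rev(starts); ends <- rev(ends)
    }
    genes[[k]] <- data.frame(gene_id = gid, contig = "chr1",
                             strand = strand, start = g_start, end = g_end,
                             stringsAsFactors = FALSE)
    regions[[k]] <- data.frame(gene_id = gid, kind = kinds,
                               start = starts, end = ends,
                               stringsAsFactors = FALSE)

    # --- true PASs ---------------------------------------------------
    n_pas <- sample(1:4, 1, prob = pas_count_probs)
    max_span <- utr3 - 70L
    if (n_pas > 1) {
      sp_max <- min(150L, max_span %/% (n_pas - 1L))
      if (sp_max < 70L) {
        stop("3'UTR too short to host ", n_pas, " PASs", call. = FALSE)
      }
      spacings <- 69L + sample.int(sp_max - 69L, n_pas - 1L, replace = TRUE)
    } else {
      spacings <- integer(0)
    }
    downstream <- runif(1) < downstream_pas_prob
    d_distal <- if (downstream) -sample(5:50, 1) else 10L
    d <- d_distal + c(0L, cumsum(spacings))      # distal -> proximal
    d <- rev(d)                                  # proximal -> distal
    pas <- if (strand == "+") g_end - d else g_start + d

    # usage weights >= 0.15, summing to 1
    if (n_pas == 1) {
      w <- 1
    } else {
      e <- rgamma(n_pas, shape = 2)
      w <- 0.15 + e / sum(e) * (1 - 0.15 * n_pas)
    }

    # CSE hexamers
    hex_i <- sample(nrow(hexamers), n_pas, replace = TRUE,
                    prob = hexamers$freq)
    cse_off <- -sample(14:32, n_pas, replace = TRUE)
    protected <- integer(0)
    for (j in seq_len(n_pas)) {
      chars <- plant_at_tx(chars, strand, pas[j], cse_off[j],
                           hexamers$dna[hex_i[j]])
      protected <- c(protected,
                     tx_window_coords(strand, pas[j], cse_off[j],
                                      cse_off[j] + 5L))
    }
    # planted motifs (e.g. UGUA)
    for (m in seq_along(motif_plant)) {
      pat <- names(motif_plant)[m]
      off <- motif_plant[[m]]
      for (j in seq_len(n_pas)) {
        chars <- plant_at_tx(chars, strand, pas[j], off, rna_to_dna(pat))
        protected <- c(protected,
                       tx_window_coords(strand, pas[j], off,
                                        off + nchar(pat) - 1L))
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          gene_id = gid, pas_index = j, motif = pat, offset = off,
          stringsAsFactors = FALSE)
      }
    }
    # keep +/-8 nt of each cleavage site free of tx-sense adenosine
    for (j in seq_len(n_pas)) {
      coords <- tx_window_coords(strand, pas[j], -8L, 8L)
      a_chr <- if (strand == "+") "A" else "T"
      hit <- coords[chars[coords] == a_chr & !(coords %in% protected)]
      if (length(hit)) {
        chars[hit] <- sample(setdiff(bases, a_chr), length(hit),
                             replace = TRUE)
      }
      protected <- c(protected, coords)
    }
    # scrub unplanted hexamer occurrences from each CSE search window
    planted_starts <- vapply(seq_len(n_pas), function(j) {
      tx_window_coords(strand, pas[j], cse_off[j], cse_off[j])[1]
    }, integer(1))
    for (j in seq_len(n_pas)) {
      for (iter in 1:12) {
        win <- tx_window_coords(strand, pas[j], -50L, -1L)
        wseq <- paste(chars[win], collapse = "")
        if (strand == "-") wseq <- revcomp(wseq)
        mutated <- FALSE
        for (hx in hexamers$dna) {
          st <- gregexpr(hx, wseq, fixed = TRUE)[[1]]
          st <- st[st > 0 & st <= 45L]   # fully inside the 50-nt window
          for (s in st) {
            gcoords <- tx_window_coords(strand, pas[j], -51L + s,
                                        -51L + s + 5L)
            if (gcoords[1] %in% planted_starts) next
            free <- gcoords[!(gcoords %in% protected)]
            if (!length(free)) next
            tgt <- free[ceiling(length(free) / 2)]
            cur <- chars[tgt]
            chars[tgt] <- sample(setdiff(bases, cur), 1)
            mutated <- TRUE
          }
        }
        if (!mutated) break
      }
    }

    pas_rows[[k]] <- data.frame(
      gene_id = gid, contig = "chr1", strand = strand, position = pas,
      pas_index = seq_len(n_pas), n_pas = n_pas, weight = w,
      cse = hexamers$hexamer[hex_i], cse_offset = cse_off,
      downstream = c(rep(FALSE, n_pas - 1L), downstream),
      stringsAsFactors = FALSE)

    # --- planted A-stretches -----------------------------------------
    if (a_stretch_rate >= 1) {
      # one artifact seed inside the 3'UTR, >= 40 nt (tx) from any PAS
      utr_reg <- regions[[k]][regions[[k]]$kind == "3UTR", ]
      cand <- utr_reg$start:utr_reg$end
      len_a <- sample(12:15, 1)
      ok <- vapply(cand, function(p) {
        all(abs(p - pas) > 40) & all(abs(p + len_a - 1L - pas) > 40) &
          !any(p:(p + len_a - 1L) %in% protected)
      }, logical(1))
      cand <- cand[ok & (cand + len_a - 1L) <= utr_reg$end]
      if (length(cand)) {
        p0 <- cand[sample.int(length(cand), 1)]
        a_chr <- if (strand == "+") "A" else "T"
        chars[p0:(p0 + len_a - 1L)] <- a_chr
        stretch_rows[[length(stretch_rows) + 1L]] <- data.frame(
          contig = "chr1", strand = strand, start = p0,
          end = p0 + len_a - 1L, gene_id = gid, in_gene = TRUE,
          stringsAsFactors = FALSE)
      }
      if (a_stretch_rate >= 2) {
        for (extra in seq_len(a_stretch_rate - 1L)) {
          len_a <- sample(12:15, 1)
          p0 <- g_start - pad - 1L + sample(20:(pad - 20L), 1)
          chars[p0:(p0 + len_a - 1L)] <- "A"
          stretch_rows[[length(stretch_rows) + 1L]] <- data.frame(
            contig = "chr1", strand = "+", start = p0,
            end = p0 + len_a - 1L, gene_id = NA_character_,
            in_gene = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  chars <- c(chars, sample(bases, pad, replace = TRUE))

  pas_df <- do.call(rbind, pas_rows)
  # pas_type from within-gene ordering (transcription direction)
  pas_df$pas_type <- NA_character_
  for (gid in unique(pas_df$gene_id)) {
    i <- which(pas_df$gene_id == gid)
    n <- length(i)
    pas_df$pas_type[i] <- if (n == 1) "sPAS" else {
      c("pPAS", rep("oPAS", n - 2L), "dPAS")
    }
  }

  off <- (xlink_peak_offset - 12L):(xlink_peak_offset + 12L)
  rel <- exp(-(off - xlink_peak_offset)^2 / (2 * xlink_peak_sd^2))
  xlink_profile <- data.frame(offset = off, rel_rate = rel / sum(rel))

  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chr1"
  models <- gene_models(do.call(rbind, genes), do.call(rbind, regions))
  truth <- structure(list(
    pas = pas_df,
    motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(gene_id = character(), pas_index = integer(),
                 motif = character(), offset = integer()),
    a_stretches = if (length(stretch_rows)) do.call(rbind, stretch_rows) else
      data.frame(contig = character(), strand = character(),
                 start = integer(), end = integer(),
                 gene_id = character(), in_gene = logical()),
    xlink_profile = xlink_profile), class = "truth_set")

  list(genome = genome, models = models, truth = truth,
       config = list(n_genes = n_genes, strand_mix = strand_mix,
                     utr_length_range = utr_length_range,
                     a_stretch_rate = a_stretch_rate,
                     pas_count_probs = pas_count_probs,
                     downstream_pas_prob = downstream_pas_prob,
                     motif_plant = motif_plant,
                     xlink_peak_offset = xlink_peak_offset,
                     xlink_peak_sd = xlink_peak_sd, seed = seed))
}
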