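# Simulated MACE-like reads: genomic insert + genuine non-templated
# poly(A) tail (jittered cleavage), plus internal-priming artifact reads
# whose trailing A's are templated from planted genomic A-stretches.

#' Simulate MACE-like 3' end reads with known ground truth
#'
#' For every sample in `samples`, each gene receives
#' `reads_per_pas * n_pas` genuine reads, multinomially split over its
#' true PASs according to the truth usage weights. A genuine read is the
#' transcript-sense genomic sequence ending 1 nt upstream of its
#' (Gaussian-jittered, rounded) cleavage site, followed by a
#' non-templated poly(A) tail of length drawn from `tail_length_range`
#' (each tail base flipped to a non-A with probability
#' `tail_error_rate`). Internal-priming reads instead run 12 nt into a
#' planted transcript-sense A-stretch, so their trailing A's are
#' templated; they make up `internal_priming_fraction` of each sample's
#' reads. PCR duplicates (same UMI and coordinates) are added at rate
#' `duplicate_rate`. UMIs are 8-nt random tags carried in the read name.
#'
#' @param sim result of [simulate_genome()].
#' @param samples data.frame with columns `sample_id`, `condition`.
#' @param reads_per_pas genuine reads per true PAS per sample (>= 1).
#' @param tail_length_range min/max non-templated tail length.
#' @param cleavage_jitter_sd sd (nt) of cleavage-site jitter (>= 0).
#' @param internal_priming_fraction fraction of reads that are
#'   internal-priming artifacts.
#' @param duplicate_rate probability that a read gains one PCR duplicate.
#' @param tail_error_rate per-base error rate inside the tail.
#' @param insert_length genomic insert length in nt.
#' @param seed integer seed.
#' @return list with `reads` (one row per read: `read_id`, `umi`,
#'   `sample_id`, `contig`, `strand`, `seq`, `read3p` [genomic position
#'   of the poly(A)-trimmed 3' end], `cleavage` [genomic cleavage-event
#'   position], `gene_id`, `pas_index`, `is_artifact`, `is_duplicate`)
#'   and `samples`.
#' @export
simulate_mace_reads <- function(sim,
                                samples = data.frame(
                                  sample_id = c("ctrl_1", "ctrl_2",
                                                "kd_1", "kd_2"),
                                  condition = c("ctrl", "ctrl",
                                                "kd", "kd"),
                                  stringsAsFactors = FALSE),
                                reads_per_pas = 20,
                                tail_length_range = c(12, 20),
                                cleavage_jitter_sd = 1,
                                internal_priming_fraction = 0,
                                duplicate_rate = 0,
                                tail_error_rate = 0,
                                insert_length = 50,
                                seed = 1L) {
  stopifnot(reads_per_pas >= 1)
  if (cleavage_jitter_sd < 0) stop("cleavage_jitter_sd must be >= 0",
                                   call. = FALSE)
  if (internal_priming_fraction < 0 || internal_priming_fraction >= 1) {
    stop("internal_priming_fraction must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  genome <- sim$genome
  truth <- sim$truth
  pas <- truth$pas
  bases <- c("A", "C", "G", "T")
  seeds_art <- truth$a_stretches[truth$a_stretches$in_gene, , drop = FALSE]

  make_umi <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(bases, 8, replace = TRUE), collapse = "")
    }, "")
  }

  rows <- list()
  rid <- 0L
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    for (gid in unique(pas$gene_id)) {
      gp <- pas[pas$gene_id == gid, , drop = FALSE]
      n_gene <- as.integer(round(reads_per_pas * nrow(gp)))
      alloc <- as.integer(rmultinom(1, n_gene, gp$weight))
      for (j in seq_len(nrow(gp))) {
        if (alloc[j] == 0) next
        strand <- gp$strand[j]
        jit <- as.integer(round(rnorm(alloc[j], 0, cleavage_jitter_sd)))
        cleav <- tx_shift(gp$position[j], jit, strand)
        for (r in seq_along(cleav)) {
          rid <- rid + 1L
          read3p <- tx_shift(cleav[r], -1L, strand)
          lo <- if (strand == "+") read3p - insert_length + 1L else read3p
          hi <- if (strand == "+") read3p else read3p + insert_length - 1L
          ins <- extract_tx_seq(genome, gp$contig[j], strand, lo, hi)$seq
          tl <- tail_length_range[1] +
            sample.int(tail_length_range[2] - tail_length_range[1] + 1L, 1) - 1L
          tail <- rep("A", tl)
          if (tail_error_rate > 0) {
            err <- runif(tl) < tail_error_rate
            if (any(err)) {
              tail[err] <- sample(c("C", "G", "T"), sum(err),
                                  replace = TRUE)
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = sprintf("read%06d", rid), umi = make_umi(1),
            sample_id = sid, contig = gp$contig[j], strand = strand,
            seq = paste0(ins, paste(tail, collapse = "")),
            read3p = read3p, cleavage = cleav[r], gene_id = gid,
            pas_index = gp$pas_index[j], is_artifact = FALSE,
            is_duplicate = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    # internal-priming artifacts
    n_genuine <- sum(vapply(rows, function(x) x$sample_id == sid,
                            logical(1)))
    f <- internal_priming_fraction
    n_art <- as.integer(round(f / (1 - f) * n_genuine))
    if (n_art > 0 && nrow(seeds_art) == 0) {
      warning("no in-gene A-stretches planted; skipping artifact reads",
              call. = FALSE)
      n_art <- 0L
    }
    if (n_art > 0) {
      pick <- sample.int(nrow(seeds_art), n_art, replace = TRUE)
      for (r in seq_len(n_art)) {
        rid <- rid + 1L
        st <- seeds_art[pick[r], ]
        strand <- st$strand
        # transcript-sense first base of the stretch
        a_start <- if (strand == "+") st$start else st$end
        # the read sequence runs 12 nt into the stretch (templated A's),
        # but tail trimming precedes alignment, so the aligned 3' end of
        # the trimmed read is the base just upstream of the stretch
        read3p <- tx_shift(a_start, -1L, strand)
        seq_end <- tx_shift(a_start, 11L, strand)
        lo <- if (strand == "+") seq_end - insert_length - 11L else seq_end
        hi <- if (strand == "+") seq_end else seq_end + insert_length + 11L
        ins <- extract_tx_seq(genome, st$contig, strand, lo, hi)$seq
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("read%06d", rid), umi = make_umi(1),
          sample_id = sid, contig = st$contig, strand = strand,
          seq = ins, read3p = read3p,
          cleavage = tx_shift(read3p, 1L, strand),
          gene_id = st$gene_id, pas_index = NA_integer_,
          is_artifact = TRUE, is_duplicate = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, rows)

  if (duplicate_rate > 0) {
    dup <- runif(nrow(reads)) < duplicate_rate
    if (any(dup)) {
      extra <- reads[dup, , drop = FALSE]
      extra$read_id <- paste0(extra$read_id, ".dup")
      extra$is_duplicate <- TRUE
      reads <- rbind(reads, extra)
    }
  }
  rownames(reads) <- NULL
  list(reads = reads, samples = samples)
}

#' Write simulated reads as FASTQ
#'
#' Read names carry the UMI as `read_id:UMI`; qualities are constant
#' Phred 40 ("I").
#'
#' @param reads the `reads` data.frame from [simulate_mace_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_mace_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(
      paste0("@", reads$read_id[i], ":", reads$umi[i]),
      reads$seq[i], "+",
      strrep("I", nchar(reads$seq[i]))), con)
  }
  invisible(path)
}

#' Read a MACE-like FASTQ with UMIs in read names
#'
#' @param path FASTQ path; read names must be `read_id:UMI`.
#' @return data.frame with `read_id`, `umi`, `seq`, `qual`.
#' @export
read_mace_fastq <- function(path) {
  q <- Biostrings::readQualityScaledDNAStringSet(path)
  nm <- names(q)
  parts <- strsplit(nm, ":", fixed = TRUE)
  data.frame(
    read_id = vapply(parts, `[`, "", 1L),
    umi = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    seq = as.character(q),
    qual = as.character(Biostrings::quality(q)),
    stringsAsFactors = FALSE)
}

#' Write the per-read aligned 3' end truth as BED6
#'
#' One interval per read at the poly(A)-trimmed 3' end position; name =
#' read id, score = 1. This bypasses alignment (out of scope): the BED
#' comes from the simulated truth, not from mapping.
#'
#' @param reads the `reads` data.frame from [simulate_mace_reads()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_read3p_bed <- function(reads, path) {
  o <- order(reads$contig, reads$read3p)
  reads <- reads[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = reads$contig,
    ranges = IRanges::IRanges(reads$read3p, width = 1L),
    strand = reads$strand)
  S4Vectors::mcols(gr)$name <- reads$read_id
  S4Vectors::mcols(gr)$score <- 1
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
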