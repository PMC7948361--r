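#' Gene model container
#'
#' A light container describing gene structures: one row per gene (span,
#' strand) plus one row per region of kind 5UTR/CDS/intron/3UTR. All
#' coordinates are 1-based inclusive.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`
#'   ("+"/"-"), `start`, `end`.
#' @param regions data.frame with columns `gene_id`, `kind` (one of
#'   "5UTR", "CDS", "intron", "3UTR"), `start`, `end`.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, regions) {
  need_g <- c("gene_id", "contig", "strand", "start", "end")
  need_r <- c("gene_id", "kind", "start", "end")
  stopifnot(all(need_g %in% names(genes)), all(need_r %in% names(regions)))
  genes <- as.data.frame(genes)[need_g]
  regions <- as.data.frame(regions)[need_r]
  check_strand(genes$strand)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(regions$kind %in% c("5UTR", "CDS", "intron", "3UTR"))) {
    stop("unknown region kind", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("region with negative length", call. = FALSE)
  }
  span <- genes[match(regions$gene_id, genes$gene_id), ]
  if (any(is.na(span$gene_id))) stop("region for unknown gene", call. = FALSE)
  if (any(regions$start < span$start | regions$end > span$end)) {
    stop("region outside gene span", call. = FALSE)
  }
  structure(list(genes = genes, regions = regions), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$regions), "regions on",
      length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

# Genomic position of the annotated 3' end of each gene.
gene_3p_end <- function(models) {
  g <- models$genes
  ifelse(g$strand == "+", g$end, g$start)
}

#' Read a GTF annotation into gene models
#'
#' Parses a GTF/GFF-style annotation (1-based inclusive on disk) into a
#' [gene_models] object. Introns are derived as the gaps between exons of
#' a gene; 5'UTR, CDS and 3'UTR regions come from the corresponding
#' feature rows. Genes without a "+"/"-" strand are rejected with a
#' warning.
#'
#' @param path path to a GTF file.
#' @return a [gene_models] object.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("malformed GTF line ", i, " in ", path, call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  no_strand <- unique(df$gene_id[!df$strand %in% c("+", "-")])
  if (length(no_strand)) {
    warning("rejecting ", length(no_strand), " gene(s) without strand",
            call. = FALSE)
    df <- df[!df$gene_id %in% no_strand, , drop = FALSE]
  }
  if (!nrow(df)) stop("no stranded genes in ", path, call. = FALSE)

  kinds <- c(five_prime_utr = "5UTR", CDS = "CDS",
             three_prime_utr = "3UTR")
  ids <- unique(df$gene_id)
  genes_l <- vector("list", length(ids))
  regions_l <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- df[df$gene_id == ids[k], , drop = FALSE]
    span <- sub[sub$type == "gene", , drop = FALSE]
    if (nrow(span)) {
      g_start <- span$start[1]; g_end <- span$end[1]
    } else {
      g_start <- min(sub$start); g_end <- max(sub$end)
    }
    genes_l[[k]] <- data.frame(
      gene_id = ids[k], contig = sub$seqnames[1], strand = sub$strand[1],
      start = g_start, end = g_end, stringsAsFactors = FALSE)
    reg <- sub[sub$type %in% names(kinds), , drop = FALSE]
    regs <- if (nrow(reg)) {
      data.frame(gene_id = ids[k], kind = unname(kinds[reg$type]),
                 start = reg$start, end = reg$end, stringsAsFactors = FALSE)
    } else NULL
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) >= 2L) {
      ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
      gaps <- IRanges::gaps(ir)
      if (length(gaps)) {
        regs <- rbind(regs, data.frame(
          gene_id = ids[k], kind = "intron",
          start = IRanges::start(gaps), end = IRanges::end(gaps),
          stringsAsFactors = FALSE))
      }
    }
    regions_l[[k]] <- regs
  }
  gene_models(do.call(rbind, genes_l),
              do.call(rbind, regions_l) %||%
                data.frame(gene_id = character(), kind = character(),
                           start = integer(), end = integer()))
}

#' Write gene models to a GTF file
#'
#' Emits gene, exon (gene span minus introns), CDS, five_prime_utr and
#' three_prime_utr features with 1-based inclusive coordinates, so that
#' `read_annotation(write_annotation(x, f))` round-trips.
#'
#' @param models a [gene_models] object.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  rows <- list()
  for (k in seq_len(nrow(models$genes))) {
    g <- models$genes[k, ]
    reg <- models$regions[models$regions$gene_id == g$gene_id, , drop = FALSE]
    feat <- data.frame(type = "gene", start = g$start, end = g$end)
    intr <- reg[reg$kind == "intron", , drop = FALSE]
    span <- IRanges::IRanges(g$start, g$end)
    exons <- if (nrow(intr)) {
      IRanges::setdiff(span, IRanges::IRanges(intr$start, intr$end))
    } else span
    feat <- rbind(feat, data.frame(type = "exon",
                                   start = IRanges::start(exons),
                                   end = IRanges::end(exons)))
    kmap <- c(`5UTR` = "five_prime_utr", CDS = "CDS",
              `3UTR` = "three_prime_utr")
    other <- reg[reg$kind != "intron", , drop = FALSE]
    if (nrow(other)) {
      feat <- rbind(feat, data.frame(type = unname(kmap[other$kind]),
                                     start = other$start, end = other$end))
    }
    feat$gene_id <- g$gene_id
    feat$contig <- g$contig
    feat$strand <- g$strand
    rows[[k]] <- feat
  }
  all <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = all$contig,
    ranges = IRanges::IRanges(all$start, all$end),
    strand = all$strand)
  S4Vectors::mcols(gr)$source <- "pasatlas"
  S4Vectors::mcols(gr)$type <- all$type
  S4Vectors::mcols(gr)$gene_id <- all$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
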