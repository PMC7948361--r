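#' Simulate iCLIP crosslink tracks around true PASs
#'
#' Per library, background crosslink events are drawn as a Poisson rain
#' (`background_rate` events per nucleotide of gene span) and each true
#' PAS receives an enrichment bump: `depth` expected events distributed
#' over the truth set's per-PAS crosslink profile (by default a Gaussian
#' bump centered 75 nt upstream of the cleavage site). Fully
#' reproducible from `seed`.
#'
#' @param sim result of [simulate_genome()].
#' @param libraries character vector of library ids.
#' @param depth expected bump events per PAS per library.
#' @param background_rate expected background events per nt per library
#'   (>= 0).
#' @param pas_subset optional logical/integer index into `sim$truth$pas`
#'   restricting which PASs receive a bump.
#' @param seed integer seed.
#' @return named list of [crosslink_track] objects, one per library.
#' @export
simulate_crosslinks <- function(sim, libraries = c("iclip_A", "iclip_B"),
                                depth = 60, background_rate = 0.001,
                                pas_subset = NULL, seed = 1L) {
  if (depth < 0 || background_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  truth <- sim$truth
  models <- sim$models
  pas <- truth$pas
  if (!is.null(pas_subset)) pas <- pas[pas_subset, , drop = FALSE]
  prof <- truth$xlink_profile

  out <- list()
  for (lib in libraries) {
    ev <- list()
    for (k in seq_len(nrow(models$genes))) {
      g <- models$genes[k, ]
      len <- g$end - g$start + 1L
      n_bg <- rpois(1, background_rate * len)
      if (n_bg > 0) {
        p <- g$start - 1L + sample.int(len, n_bg, replace = TRUE)
        tb <- table(p)
        ev[[length(ev) + 1L]] <- data.frame(
          contig = g$contig, strand = g$strand,
          position = as.integer(names(tb)), count = as.integer(tb),
          stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(nrow(pas))) {
      n <- rpois(1, depth)
      if (n == 0) next
      off <- sample(prof$offset, n, replace = TRUE, prob = prof$rel_rate)
      p <- tx_shift(pas$position[j], off, pas$strand[j])
      tb <- table(p)
      ev[[length(ev) + 1L]] <- data.frame(
        contig = pas$contig[j], strand = pas$strand[j],
        position = as.integer(names(tb)), count = as.integer(tb),
        stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev)
    if (is.null(events)) {
      events <- data.frame(contig = character(), strand = character(),
                           position = integer(), count = integer())
    } else {
      events <- aggregate(count ~ contig + strand + position, events, sum)
      events <- events[order(events$contig, events$strand,
                             events$position), ]
      rownames(events) <- NULL
    }
    out[[lib]] <- crosslink_track(lib, events)
  }
  out
}
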