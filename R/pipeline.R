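# End-to-end orchestration: simulate -> call-pas -> annotate ->
# motif/crosslink profiles, with a single config, structured per-stage
# logging and an output manifest.

PIPELINE_STAGES <- c("simulate", "call_pas", "annotate", "motif", "xlink")

STAGE_DEPS <- list(simulate = character(0),
                   call_pas = "simulate",
                   annotate = "call_pas",
                   motif = "annotate",
                   xlink = "annotate")

#' Build a validated pipeline configuration
#'
#' All thresholds carry the study defaults: 25-nt cluster distance,
#' 15-nt PAS windows (half width 7), CE > 4 / PU > 5 / TPM > 0.25,
#' APA thresholds FDR 0.1 and |delta PDUI| 0.05, 100 resamples /
#' permutations / shuffles, motif window +-300 nt, crosslink window
#' -400..+100 nt, profile FDR 0.01, crosslink-site FDR 0.05. The seed
#' drives every stochastic stage.
#'
#' @param seed integer seed (mandatory for the stochastic stages).
#' @param out_dir output directory.
#' @param stages enabled stages, a subset of
#'   `c("simulate", "call_pas", "annotate", "motif", "xlink")`.
#' @param ... overrides for any default field.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("pasatlas_run_"),
                            stages = PIPELINE_STAGES, ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    # simulation
    n_genes = 20L,
    reads_per_pas = 20L,
    internal_priming_fraction = 0.3,
    duplicate_rate = 0.1,
    cleavage_jitter_sd = 1,
    conditions = list(ctrl = c("ctrl_1", "ctrl_2"),
                      kd = c("kd_1", "kd_2")),
    xlink_libraries = c("iclip_A", "iclip_B"),
    xlink_depth = 60,
    xlink_background_rate = 0.001,
    # PAS calling
    phred_cutoff = 16L,
    min_a_per_window = 8L,
    artifact_adjacency_nt = 5L,
    cluster_max_dist = 25L,
    window_half_width = 7L,
    min_ce = 4,
    min_pu = 5,
    min_tpm = 0.25,
    # annotation / APA
    downstream_nt = 50L,
    cse_window_nt = 50L,
    apa_fdr = 0.1,
    min_abs_dpdui = 0.05,
    # motif / crosslink statistics
    motif_pattern = "UGUA",
    motif_half_window = 300L,
    loess_span = 0.1,
    n_resamples = 100L,
    profile_fdr = 0.01,
    xlink_window = c(-400L, 100L),
    xlink_site_fdr = 0.05,
    n_perm = 100L,
    kmer_k = 5L,
    n_shuffles = 100L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a config list (class `pipeline_config` or plain list).
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  required <- c("seed", "out_dir", "stages", "n_genes", "reads_per_pas",
                "cluster_max_dist", "window_half_width", "min_ce",
                "min_pu", "min_tpm", "apa_fdr", "min_abs_dpdui",
                "n_resamples", "motif_half_window", "xlink_window",
                "profile_fdr", "xlink_site_fdr", "n_perm")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("config field 'seed' must be a single integer", call. = FALSE)
  }
  bad_stage <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as JSON
#'
#' The config round-trips unchanged (up to numeric type width).
#'
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @return `path` / the config.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$conditions <- as.list(cfg$conditions)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

samples_from_config <- function(cfg) {
  data.frame(
    sample_id = unlist(cfg$conditions, use.names = FALSE),
    condition = rep(names(cfg$conditions),
                    vapply(cfg$conditions, length, integer(1))),
    stringsAsFactors = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order (simulate, call_pas, annotate, motif,
#' xlink); a disabled stage is skipped and any enabled stage whose
#' dependency is disabled raises an error naming both stages. All
#' outputs are written under `cfg$out_dir` and listed, with their MD5
#' hashes, in `manifest.json`; identical config + seed reruns are
#' bit-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `results` (in-memory stage outputs), `log`
#'   (per-stage record counts) and `manifest` (files + hashes),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  for (st in cfg$stages) {
    dep <- setdiff(STAGE_DEPS[[st]], cfg$stages)
    if (length(dep)) {
      stop("stage '", st, "' requires output of disabled stage '",
           dep[1], "'", call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log <- list()
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  # config.json is an input echo (it embeds out_dir), so it is referenced
  # from the manifest but not part of the hashed data outputs
  write_config(cfg, file.path(cfg$out_dir, "config.json"))

  if ("simulate" %in% cfg$stages) {
    sim <- simulate_genome(n_genes = cfg$n_genes,
                           seed = cfg$seed)
    samples <- samples_from_config(cfg)
    mace <- simulate_mace_reads(
      sim, samples = samples, reads_per_pas = cfg$reads_per_pas,
      cleavage_jitter_sd = cfg$cleavage_jitter_sd,
      internal_priming_fraction = cfg$internal_priming_fraction,
      duplicate_rate = cfg$duplicate_rate, seed = cfg$seed + 1L)
    xl <- simulate_crosslinks(
      sim, libraries = cfg$xlink_libraries, depth = cfg$xlink_depth,
      background_rate = cfg$xlink_background_rate, seed = cfg$seed + 2L)
    res$sim <- sim
    res$mace <- mace
    res$xlinks <- xl
    log$simulate <- list(
      n_genes = nrow(sim$models$genes),
      n_true_pas = nrow(sim$truth$pas),
      n_reads = nrow(mace$reads),
      n_artifact_reads = sum(mace$reads$is_artifact),
      n_xlink_events = vapply(xl, function(t) t$n_events, numeric(1)))
    write_genome(sim$genome, file.path(cfg$out_dir, "genome.fa"))
    emit(file.path(cfg$out_dir, "genome.fa"))
    write_annotation(sim$models, file.path(cfg$out_dir, "annotation.gtf"))
    emit(file.path(cfg$out_dir, "annotation.gtf"))
  }

  if ("call_pas" %in% cfg$stages) {
    sim <- res$sim
    mace <- res$mace
    positions <- data.frame(read_id = mace$reads$read_id,
                            contig = mace$reads$contig,
                            strand = mace$reads$strand,
                            position = mace$reads$read3p,
                            stringsAsFactors = FALSE)
    prep <- prepare_reads(mace$reads, positions = positions,
                          phred_cutoff = cfg$phred_cutoff)
    events <- cleavage_events_from_reads(prep)
    stretches <- find_genomic_a_stretches(sim$genome,
                                          min_a = cfg$min_a_per_window)
    filt <- filter_internal_priming(events, stretches,
                                    adjacency_nt = cfg$artifact_adjacency_nt)
    clustered <- cluster_cleavage_events(pool_events(filt$events),
                                         max_dist = cfg$cluster_max_dist)
    windows <- define_pas_windows(clustered,
                                  half_width = cfg$window_half_width)
    res$prepared <- prep
    res$events <- filt$events
    res$stretches <- stretches
    res$windows <- windows
    log$call_pas <- c(prep$log,
                      list(n_events = nrow(events),
                           n_artifact_events_removed = filt$n_removed,
                           n_windows = nrow(windows)))
    write_events_bed(filt$events, file.path(cfg$out_dir, "events.bed"))
    emit(file.path(cfg$out_dir, "events.bed"))
  }

  if ("annotate" %in% cfg$stages) {
    sim <- res$sim
    asg <- assign_gene_and_region(res$windows, sim$models,
                                  downstream_nt = cfg$downstream_nt)
    quant <- quantify_and_filter(
      asg$windows, res$events, samples_from_config(cfg), sim$models,
      min_ce = cfg$min_ce, min_pu = cfg$min_pu, min_tpm = cfg$min_tpm)
    records <- classify_pas_types(quant$windows)
    records <- assign_cse(records, sim$genome,
                          window_nt = cfg$cse_window_nt)
    res$atlas <- records
    log$annotate <- list(
      n_removed_multi = asg$n_removed_multi,
      n_removed_unassigned = asg$n_removed_unassigned,
      n_windows_filtered_out = sum(!quant$table$pass),
      n_pas = nrow(records))
    write_tsv(records, file.path(cfg$out_dir, "pas_atlas.tsv"))
    emit(file.path(cfg$out_dir, "pas_atlas.tsv"))
    write_pas_bed(records, file.path(cfg$out_dir, "pas_atlas.bed"))
    emit(file.path(cfg$out_dir, "pas_atlas.bed"))
  }

  if ("motif" %in% cfg$stages) {
    anchors <- res$atlas
    prof <- motif_metaprofile(anchors, res$sim$genome,
                              cfg$motif_pattern,
                              half_window = cfg$motif_half_window,
                              span = cfg$loess_span)
    res$motif_profile <- prof
    log$motif <- list(n_anchors = attr(prof, "n_anchors"))
    write_tsv(as.data.frame(prof),
              file.path(cfg$out_dir, "motif_profile.tsv"))
    emit(file.path(cfg$out_dir, "motif_profile.tsv"))
  }

  if ("xlink" %in% cfg$stages) {
    anchors <- res$atlas
    tracks <- res$xlinks
    prof <- pas_metaprofile(tracks[[1]], anchors,
                            window = cfg$xlink_window,
                            span = cfg$loess_span)
    res$xlink_metaprofile <- prof
    if (length(tracks) >= 2L) {
      cmp <- compare_profiles(tracks[[1]], tracks[[2]], anchors,
                              window = cfg$xlink_window,
                              fdr = cfg$profile_fdr)
      res$xlink_comparison <- cmp
      write_tsv(cmp$table, file.path(cfg$out_dir, "xlink_comparison.tsv"))
      emit(file.path(cfg$out_dir, "xlink_comparison.tsv"))
    }
    sig <- call_significant_xlinks(tracks[[1]], res$sim$models,
                                   n_perm = cfg$n_perm,
                                   fdr = cfg$xlink_site_fdr,
                                   seed = cfg$seed + 3L)
    res$xlink_sites <- sig
    log$xlink <- list(
      n_positions = tracks[[1]]$n_positions,
      n_significant = sum(sig$significant))
    write_tsv(as.data.frame(prof),
              file.path(cfg$out_dir, "xlink_profile.tsv"))
    emit(file.path(cfg$out_dir, "xlink_profile.tsv"))
    write_tsv(sig, file.path(cfg$out_dir, "xlink_sites.tsv"))
    emit(file.path(cfg$out_dir, "xlink_sites.tsv"))
  }

  manifest <- list(
    config = "config.json",
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE),
    log = log)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = res, log = log, manifest = manifest))
}
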