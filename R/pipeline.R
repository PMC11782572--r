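# Workflow orchestration ---------------------------------------------------
#
# Thin glue over the module functions: simulate -> features -> dataset ->
# search/train/evaluate, with one flat validated config, derived per-stage
# seeds and JSON manifests beside every artifact. The same functions back
# the command-line wrapper in inst/cli/exonscan.R.

.config_defaults <- function() {
  list(
    n_sequences = 10L, exon_length_range = c(300L, 600L),
    intron_length_range = c(600L, 1500L), exons_per_sequence_range = c(3L, 5L),
    codon_bias_strength = 0.9, gc_content = 0.5,
    scales_min = 9, scales_max = 400, n_scales = 24L,
    scale_reduction = "max", baseline = "mgwt", window_length = 351L,
    frame_length = 256L, overlap = 100L, framing = "per_class",
    train_fraction = 0.8,
    population_size = 10L, max_iterations = 20L,
    search_epochs = 10L, final_epochs = 10L, learning_rate = 0.001,
    Q1 = 0.6, Q2 = 0.4, Q3 = 0.6, L1 = 0.8, L2 = 0.2, w = 2.5,
    seed = 1L)
}

#' Validated flat pipeline configuration
#'
#' Defaults mirror the reference settings (AVOA parameters, hyperparameter
#' ranges, training options) plus the synthetic-genome study conditions.
#' Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `exonscan_config`.
#' @export
exonscan_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  if (!cfg$baseline %in% c("mgwt", "stdft")) {
    stop_field("baseline", "must be 'mgwt' or 'stdft'")
  }
  structure(cfg, class = "exonscan_config")
}

.cfg_grid <- function(cfg) {
  scale_grid(exp(seq(log(cfg$scales_min), log(cfg$scales_max),
                     length.out = cfg$n_scales)))
}

.write_manifest <- function(obj, path) {
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Simulate genomes and write FASTA/BED fixtures
#'
#' @param cfg an [exonscan_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the list of generated sequences; writes
#'   `genome.fasta`, `exons.bed` and `simulate_manifest.json`.
#' @export
pipeline_simulate <- function(cfg = exonscan_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_genome_spec(
    n_sequences = cfg$n_sequences,
    exon_length_range = cfg$exon_length_range,
    intron_length_range = cfg$intron_length_range,
    exons_per_sequence_range = cfg$exons_per_sequence_range,
    codon_bias_strength = cfg$codon_bias_strength,
    gc_content = cfg$gc_content,
    seed = derive_seed(cfg$seed, 21L))
  seqs <- generate_genome(spec)
  write_fasta(seqs, file.path(out_dir, "genome.fasta"))
  write_bed(seqs, file.path(out_dir, "exons.bed"))
  .write_manifest(list(
    n_sequences = length(seqs),
    total_bases = sum(vapply(seqs, function(s) nchar(s$sequence), numeric(1))),
    n_exons = sum(vapply(seqs, function(s) nrow(s$exons), numeric(1))),
    codon_bias_strength = cfg$codon_bias_strength,
    seed = spec$seed), file.path(out_dir, "simulate_manifest.json"))
  invisible(seqs)
}

#' Compute normalized spectral profiles for a FASTA/BED pair
#'
#' Voss mapping, then the Gabor wavelet spectrum (or the ST-DFT baseline
#' when `cfg$baseline == "stdft"`), min-max normalized per sequence.
#' Sequences without annotation are skipped with a warning.
#'
#' @param cfg an [exonscan_config()].
#' @param fasta,bed input paths.
#' @param out_dir optional directory for 2-column TSV profiles.
#' @return named list of `spectrum_profile`s with per-position labels
#'   attached as attribute `labels`.
#' @export
pipeline_features <- function(cfg, fasta, bed, out_dir = NULL) {
  seqs <- read_fasta(fasta)
  ann <- read_annotations(bed, vapply(seqs, nchar, integer(1)))
  grid <- .cfg_grid(cfg)
  profiles <- list()
  for (id in names(seqs)) {
    if (!id %in% names(ann)) {
      warning(sprintf("no annotation for sequence '%s'; skipped", id),
              call. = FALSE)
      next
    }
    ind <- voss_map(seqs[[id]], id = id)
    prof <- if (cfg$baseline == "mgwt") {
      mgwt_spectrum(ind, grid, scale_reduction = cfg$scale_reduction)
    } else {
      stdft_spectrum(ind, cfg$window_length)
    }
    prof <- normalize_profile(prof)
    attr(prof, "labels") <- position_labels(ann[[id]], nchar(seqs[[id]]))
    profiles[[id]] <- prof
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(
        data.frame(position = seq_along(prof$values) - 1L,
                   value = prof$values),
        file.path(out_dir, paste0(id, ".profile.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  profiles
}

#' Frame labeled profiles into a split dataset
#'
#' @param cfg an [exonscan_config()].
#' @param profiles output of [pipeline_features()].
#' @param out_dir optional directory for the frame-metadata CSV and
#'   manifest.
#' @return a `frame_dataset`.
#' @export
pipeline_dataset <- function(cfg, profiles, out_dir = NULL) {
  frames <- list()
  for (prof in profiles) {
    frames <- c(frames, if (identical(cfg$framing, "sliding")) {
      extract_frames(prof, attr(prof, "labels"), cfg$frame_length,
                     cfg$overlap)
    } else {
      class_stream_frames(prof, attr(prof, "labels"), cfg$frame_length,
                          cfg$overlap)
    })
  }
  ds <- shuffle_split(frames, cfg$train_fraction,
                      seed = derive_seed(cfg$seed, 22L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    labels <- vapply(ds$frames, `[[`, integer(1), "label")
    meta <- data.frame(
      index = seq_along(ds$frames),
      source_id = vapply(ds$frames, `[[`, character(1), "source_id"),
      start = vapply(ds$frames, `[[`, integer(1), "start"),
      label = labels,
      split = ifelse(seq_along(ds$frames) %in% ds$train, "train", "test"))
    utils::write.csv(meta, file.path(out_dir, "frames.csv"),
                     row.names = FALSE)
    .write_manifest(list(
      n_frames = length(ds$frames),
      n_train = length(ds$train), n_test = length(ds$test),
      class_counts = as.list(table(labels)),
      seed = ds$seed), file.path(out_dir, "dataset_manifest.json"))
  }
  ds
}

#' Run the whole pipeline: simulate, features, dataset, search, evaluate
#'
#' @param cfg an [exonscan_config()].
#' @param out_dir directory for artifacts (experiment record, metrics).
#' @return the fitted `exon_cnn`.
#' @export
pipeline_run <- function(cfg = exonscan_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- pipeline_simulate(cfg, out_dir)
  profiles <- pipeline_features(cfg, file.path(out_dir, "genome.fasta"),
                                file.path(out_dir, "exons.bed"))
  ds <- pipeline_dataset(cfg, profiles, out_dir)
  fit <- exon_cnn(ds,
                  population_size = cfg$population_size,
                  max_iterations = cfg$max_iterations,
                  search_epochs = cfg$search_epochs,
                  final_epochs = cfg$final_epochs,
                  learning_rate = cfg$learning_rate,
                  seed = derive_seed(cfg$seed, 23L),
                  avoa_args = list(Q1 = cfg$Q1, Q2 = cfg$Q2, Q3 = cfg$Q3,
                                   L1 = cfg$L1, L2 = cfg$L2, w = cfg$w))
  experiment_record(fit, file.path(out_dir, "experiment_record.json"))
  write_history(fit$stage1, file.path(out_dir, "stage1_history.csv"))
  write_history(fit$stage2, file.path(out_dir, "stage2_history.csv"))
  fit
}
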