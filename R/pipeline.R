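#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Each knob records, next to the
#' active value, the study-scale reference default (full 1-kHz epochs, 100
#' pseudo-trial iterations, 1000 bootstraps, the 50-sample onset criterion);
#' the active defaults are a desk-scale configuration that exercises every
#' stage in seconds.
#'
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @param output_dir where stage outputs are written.
#' @param n_subjects,trials_per_condition,n_channels,srate,epoch_window_ms
#'   group simulation size and epoch geometry.
#' @param sensory_onset_ms,perceptual_onset_ms,sensory_snr,perceptual_snr
#'   planted effect structure (see [effect_spec]).
#' @param n_iterations,n_pseudo,C decoding knobs.
#' @param n_runs,n_features ROI pattern synthesis size.
#' @param grid_dim,radius_voxels volumetric searchlight size.
#' @param knn,bin_ms sensor searchlight knobs.
#' @param q,k_consecutive,n_boot,tail inference knobs.
#' @param n_participants,rating_noise_sd behavioral ratings synthesis.
#' @return A `run_config` (named list with a `reference` attribute).
#' @export
run_config <- function(seed = 1L, output_dir = "results/pipeline",
                       n_subjects = 3L, trials_per_condition = 20L,
                       n_channels = 16L, srate = 100,
                       epoch_window_ms = c(-100, 390),
                       sensory_onset_ms = 80, perceptual_onset_ms = 180,
                       sensory_snr = 1, perceptual_snr = 1,
                       n_iterations = 2L, n_pseudo = 5L, C = 1,
                       n_runs = 10L, n_features = 40L,
                       grid_dim = c(6L, 6L, 6L), radius_voxels = 2,
                       knn = 4L, bin_ms = 10,
                       q = 0.05, k_consecutive = 5L, n_boot = 200L,
                       tail = "greater",
                       n_participants = 19L, rating_noise_sd = 1) {
  cfg <- list(
    seed = as.integer(seed), output_dir = output_dir,
    n_subjects = n_subjects, trials_per_condition = trials_per_condition,
    n_channels = n_channels, srate = srate,
    epoch_window_ms = epoch_window_ms,
    sensory_onset_ms = sensory_onset_ms,
    perceptual_onset_ms = perceptual_onset_ms,
    sensory_snr = sensory_snr, perceptual_snr = perceptual_snr,
    n_iterations = n_iterations, n_pseudo = n_pseudo, C = C,
    n_runs = n_runs, n_features = n_features,
    grid_dim = grid_dim, radius_voxels = radius_voxels,
    knn = knn, bin_ms = bin_ms,
    q = q, k_consecutive = k_consecutive, n_boot = n_boot, tail = tail,
    n_participants = n_participants, rating_noise_sd = rating_noise_sd
  )
  attr(cfg, "reference") <- list(
    trials_per_condition = 170L, n_channels = 63L, srate = 1000,
    epoch_window_ms = c(-100, 999), n_iterations = 100L, n_pseudo = 5L,
    C = 1, radius_voxels = 4, knn = 4L, bin_ms = 10, q = 0.05,
    k_consecutive = 50L, n_boot = 1000L, n_participants = 19L
  )
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Round-trips losslessly: reading back a written config reproduces the same
#' active values and reference defaults.
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @return `read_run_config` returns the [run_config]; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(active = unclass(config),
                        reference = attr(config, "reference")), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.list(obj) || is.null(obj$active)) stop("not a run_config YAML: ", path)
  cfg <- obj$active
  for (f in c("epoch_window_ms", "grid_dim")) cfg[[f]] <- unlist(cfg[[f]])
  attr(cfg, "reference") <- obj$reference
  class(cfg) <- "run_config"
  cfg
}

pipeline_spec <- function(config) {
  effect_spec(sensory_onset_ms = config$sensory_onset_ms,
              perceptual_onset_ms = config$perceptual_onset_ms,
              sensory_snr = config$sensory_snr,
              perceptual_snr = config$perceptual_snr,
              seed = split_seed(config$seed, "spec"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — design schedules, synthetic data,
#' group time-resolved decoding, ROI decoding, volumetric and sensor
#' searchlights, RSA, group statistics — writing each stage's outputs under
#' `config$output_dir` and returning a manifest of paths and MD5 hashes.
#' Rerunning with the same config reproduces identical hashes for all
#' deterministic outputs (everything except process metadata).
#'
#' @param config a [run_config].
#' @return The run manifest (named list: per stage, output paths and
#'   hashes), also written as `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  paths <- character(0)
  spec <- pipeline_spec(config)

  # -- design: the printed experimental design, study scale
  sched_f <- generate_fmri_run_schedule(seed = split_seed(config$seed, "fmri_sched"))
  sched_e <- generate_eeg_session_schedule(seed = split_seed(config$seed, "eeg_sched"))
  paths <- c(paths, write_schedule(sched_f, out("fmri_run_schedule.tsv")),
             write_schedule(sched_e, out("eeg_session_schedule.tsv")))

  # -- simulate: behavioral ratings + one example epochs container
  ratings <- synthesize_similarity_ratings(
    n_participants = config$n_participants,
    noise_sd = config$rating_noise_sd,
    seed = split_seed(config$seed, "ratings"))
  paths <- c(paths, write_tsv(as.data.frame(unclass(ratings)), out("ratings.tsv")))
  ep1 <- simulate_subject_epochs(spec,
                                 trials_per_condition = config$trials_per_condition,
                                 seed = split_seed(config$seed, 1L),
                                 n_channels = config$n_channels,
                                 srate = config$srate,
                                 epoch_window_ms = config$epoch_window_ms)
  paths <- c(paths, write_epochs(ep1, out("subject01.epochs.rds")))

  # -- decode: group time-resolved curves
  grp <- decode_group_time_courses(
    config$n_subjects, spec, seed = config$seed,
    trials_per_condition = config$trials_per_condition,
    n_channels = config$n_channels, srate = config$srate,
    epoch_window_ms = config$epoch_window_ms,
    n_iterations = config$n_iterations, n_pseudo = config$n_pseudo,
    C = config$C, keep_pairs = TRUE)
  curves <- do.call(rbind, lapply(c("within", "across", "difference"), function(s) {
    m <- grp[[s]]
    data.frame(scheme = s, subject = rep(seq_len(nrow(m)), times = ncol(m)),
               time_ms = rep(grp$time_ms, each = nrow(m)),
               accuracy = as.vector(m))
  }))
  paths <- c(paths, write_tsv(curves, out("group_time_courses.tsv")))

  # -- roi: ROI-wise within/across/difference
  rois <- synthesize_roi_patterns(n_runs = config$n_runs, spec = spec,
                                  n_features = config$n_features)
  roi_res <- roi_decode(rois, seed = split_seed(config$seed, "roi_bins"))
  roi_tab <- do.call(rbind, lapply(names(roi_res), function(r) {
    data.frame(roi = r,
               within = grand_average(roi_res[[r]]$within),
               across = grand_average(roi_res[[r]]$across),
               difference = grand_average(roi_res[[r]]$difference))
  }))
  paths <- c(paths, write_tsv(roi_tab, out("roi_accuracies.tsv")))

  # -- searchlight: small volumetric map + sensor map
  region <- array(FALSE, config$grid_dim)
  region[seq_len(max(2L, config$grid_dim[1] %/% 3)),
         seq_len(max(2L, config$grid_dim[2] %/% 3)),
         seq_len(max(2L, config$grid_dim[3] %/% 3))] <- TRUE
  vols <- synthesize_volume_patterns(config$grid_dim, signal_region = region,
                                     spec = spec, n_runs = config$n_runs)
  vmap <- volume_searchlight(vols, radius_voxels = config$radius_voxels,
                             seed = split_seed(config$seed, "volsl"),
                             C = config$C)
  paths <- c(paths, write_accuracy_map_nifti(vmap, out("searchlight")))
  smap <- sensor_searchlight(noise_normalize(baseline_correct(ep1)),
                             k = config$knn, bin_ms = config$bin_ms,
                             seed = split_seed(config$seed, "senssl"),
                             C = config$C)
  paths <- c(paths, write_sensor_map(smap, out("sensor_searchlight.tsv")))

  # -- rsa: behavior RDM and per-subject RSA time courses
  beh <- ratings_to_rdm(ratings)
  paths <- c(paths, write_rdm(beh, out("behavior_rdm.csv")))
  rsa_tab <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
    rbind(
      data.frame(subject = s, source = "within", time_ms = grp$time_ms,
                 R = rsa_time_course(grp$within_pairs[s, , ], beh)),
      data.frame(subject = s, source = "across", time_ms = grp$time_ms,
                 R = rsa_time_course(grp$across_pairs[s, , ], beh))
    )
  }))
  paths <- c(paths, write_tsv(rsa_tab, out("rsa_time_courses.tsv")))

  # -- stats: group traces, onsets, bootstrap CIs, latency difference
  traces <- rbind(
    cbind(scheme = "within",
          significance_trace(grp$within, grp$time_ms, mu = 50,
                             tail = config$tail, q = config$q)),
    cbind(scheme = "across",
          significance_trace(grp$across, grp$time_ms, mu = 50,
                             tail = config$tail, q = config$q)),
    cbind(scheme = "difference",
          significance_trace(grp$difference, grp$time_ms, mu = 0,
                             tail = config$tail, q = config$q))
  )
  paths <- c(paths, write_tsv(traces, out("significance_traces.tsv")))
  ci_w <- bootstrap_onset_ci(grp$within, grp$time_ms, mu = 50,
                             tail = config$tail, q = config$q,
                             n_boot = config$n_boot,
                             seed = split_seed(config$seed, "boot_w"),
                             k = config$k_consecutive)
  ci_x <- bootstrap_onset_ci(grp$across, grp$time_ms, mu = 50,
                             tail = config$tail, q = config$q,
                             n_boot = config$n_boot,
                             seed = split_seed(config$seed, "boot_x"),
                             k = config$k_consecutive)
  ld <- bootstrap_latency_difference(grp$within, grp$across, grp$time_ms,
                                     tail = config$tail, q = config$q,
                                     n_boot = config$n_boot,
                                     seed = split_seed(config$seed, "boot_d"),
                                     k = config$k_consecutive)
  stats_out <- list(
    onset_within = ci_w[c("onset", "ci_low", "ci_high", "prop_undefined")],
    onset_across = ci_x[c("onset", "ci_low", "ci_high", "prop_undefined")],
    latency_difference = ld[c("diff_ms", "ci_low", "ci_high", "p",
                              "prop_undefined")],
    run = list(seed = config$seed, n_boot = config$n_boot, q = config$q,
               k_consecutive = config$k_consecutive, tail = config$tail)
  )
  stats_path <- out("stats_summary.json")
  jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, stats_path)

  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  paths <- c(paths, cfg_path)

  manifest <- list(
    output_dir = config$output_dir, seed = config$seed,
    files = data.frame(path = basename(paths),
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
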