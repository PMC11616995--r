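#!/usr/bin/env Rscript
# Stage 5: spatially unbiased maps. A volumetric sphere searchlight over a
# synthetic voxel grid with one signal-bearing region, and a nearest-channel
# sensor searchlight over the example subject's epochs.

source("analysis/_common.R")

message("== searchlight maps ==")
spec <- analysis_spec()

dims <- c(10, 10, 6)
region <- array(FALSE, dims)
region[2:4, 2:4, 2:3] <- TRUE
# pattern amplitude raised relative to the EEG stages: a radius-2 sphere
# mixes in many noise voxels at the region boundary
spec_vol <- effect_spec(sensory_snr = 2.5, perceptual_snr = 2.5,
                        seed = spec$seed)
vols <- synthesize_volume_patterns(dims, signal_region = region,
                                   spec = spec_vol,
                                   n_runs = 10, mix = 0.5, noise_sd = 1)
vmap <- volume_searchlight(vols, radius_voxels = 2,
                           seed = split_seed(MASTER_SEED, "volsl"))
write_accuracy_map_nifti(vmap, res_path("searchlight"), voxel_size_mm = 3)
message("  wrote ", res_path("searchlight_{within,across}.nii.gz"))

for (s in c("within", "across")) {
  acc <- vmap$maps[[s]]
  message(sprintf("  %s: signal region mean %.1f%%, elsewhere %.1f%%",
                  s, mean(acc[region]), mean(acc[!region])))
  cl <- threshold_clusters(acc, threshold = 60)
  if (nrow(cl) > 0) {
    message(sprintf("    %d cluster(s) above 60%%; largest %d voxels, peak %.1f%%",
                    nrow(cl), max(cl$n_voxels), max(cl$peak)))
  }
}

ep <- read_epochs(res_path("subject01.epochs.rds"))
ep <- noise_normalize(baseline_correct(ep))
smap <- sensor_searchlight(ep, k = 4, bin_ms = 10,
                           n_iterations = 1,
                           seed = split_seed(MASTER_SEED, "senssl"))
write_sensor_map(smap, res_path("sensor_searchlight.tsv"))
best <- which(smap$maps$within == max(smap$maps$within), arr.ind = TRUE)[1, ]
message(sprintf("  sensor map: peak within-hand accuracy %.1f%% at channel %s, bin starting %d ms",
                max(smap$maps$within), smap$channels[best[1]],
                smap$bin_start_ms[best[2]]))
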