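#!/usr/bin/env Rscript
# Stage 2: synthesize the study's data modalities — an example subject's
# EEG-like epochs, fMRI-like ROI pattern sets, and behavioral similarity
# ratings — from one planted effect specification.

source("analysis/_common.R")

message("== synthetic data ==")
spec <- analysis_spec()

ep <- simulate_subject_epochs(spec, trials_per_condition = TRIALS_PER_CONDITION,
                              seed = split_seed(MASTER_SEED, 1L),
                              n_channels = N_CHANNELS, srate = SRATE,
                              epoch_window_ms = EPOCH_WINDOW_MS)
write_epochs(ep, res_path("subject01.epochs.rds"))
message(sprintf("  example subject: %d trials x %d channels x %d samples",
                dim(ep)[1], dim(ep)[2], dim(ep)[3]))

rois <- synthesize_roi_patterns(n_runs = 10, spec = spec, n_features = 60)
message("  ROI pattern sets (runs x 16 x voxels): ",
        paste(names(rois), collapse = ", "))
mix_tab <- data.frame(roi = names(default_roi_mixes()),
                      hand_dependence_mix = unname(default_roi_mixes()))
save_tsv(mix_tab, "roi_mixes.tsv")

ratings <- synthesize_similarity_ratings(
  n_participants = 19, noise_sd = 1,
  seed = split_seed(MASTER_SEED, "ratings"))
save_tsv(as.data.frame(unclass(ratings)), "ratings.tsv")
beh <- ratings_to_rdm(ratings)
write_rdm(beh, res_path("behavior_rdm.csv"))
message(sprintf("  19 raters x 28 pairs; behavior RDM vs planted geometry Spearman R = %.3f",
                rdm_correlation(beh, rdm(braille_letter_geometry()))))
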