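# Shared settings for the numbered analysis drivers.
#
# One master seed feeds every stage; each driver derives its own stream with
# split_seed(). Simulation sizes are a desk-scale version of the study
# design: 12 subjects, 16 channels, 100-Hz epochs over (-100, 390) ms (50
# samples), 20 trials per condition binned into 5 pseudo-trials, 5
# pseudo-trial iterations. The planted effect places the hand-dependent
# (sensory) code at 80 ms and the hand-independent (perceptual) code at
# 180 ms.

suppressPackageStartupMessages(library(braillemvpa))

MASTER_SEED <- 20240
RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

N_SUBJECTS <- 12L
TRIALS_PER_CONDITION <- 20L
N_CHANNELS <- 16L
SRATE <- 100
EPOCH_WINDOW_MS <- c(-100, 390)
N_ITERATIONS <- 5L
K_CONSEC <- 5L      # 50 ms at the 10-ms sample spacing
Q_FDR <- 0.05
N_BOOT <- 1000L

analysis_spec <- function() {
  effect_spec(sensory_onset_ms = 80, perceptual_onset_ms = 180,
              sensory_snr = 1.2, perceptual_snr = 1.2)
}

res_path <- function(...) file.path(RESULTS_DIR, ...)

save_tsv <- function(df, name) {
  path <- res_path(name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
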