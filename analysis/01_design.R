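#!/usr/bin/env Rscript
# Stage 1: generate the experimental schedules at study scale and verify the
# printed design quantities.

source("analysis/_common.R")

message("== experiment design ==")

fmri <- generate_fmri_run_schedule(seed = split_seed(MASTER_SEED, "fmri"))
eeg <- generate_eeg_session_schedule(seed = split_seed(MASTER_SEED, "eeg"))

write_schedule(fmri, res_path("fmri_run_schedule.tsv"))
write_schedule(eeg, res_path("eeg_session_schedule.tsv"))

comp_f <- schedule_composition(fmri)
comp_e <- schedule_composition(eeg)
reg <- eeg[eeg$kind == "regular", ]

summary <- data.frame(
  quantity = c("fmri trials per run", "fmri regular", "fmri catch",
               "fmri null", "eeg trials per session", "eeg regular",
               "eeg catch", "eeg repetitions per condition",
               "localizer block duration (s)"),
  value = c(nrow(fmri), comp_f[["regular"]], comp_f[["catch"]],
            comp_f[["null"]], nrow(eeg), comp_e[["regular"]],
            comp_e[["catch"]], max(table(reg$letter, reg$hand)),
            localizer_block_duration())
)
save_tsv(summary, "design_summary.tsv")

stopifnot(nrow(fmri) == 107L, nrow(eeg) == 3261L,
          all(table(reg$letter, reg$hand) == 170L))
message("  one fMRI run: ", nrow(fmri), " trials (",
        paste(comp_f, collapse = "/"), " regular/catch/null)")
message("  one EEG session: ", nrow(eeg), " trials, every condition ",
        max(table(reg$letter, reg$hand)), "x")
message("  all printed design counts verified")
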