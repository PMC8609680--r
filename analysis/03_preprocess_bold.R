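#!/usr/bin/env Rscript
# Condition the simulated parcellated BOLD: drop the first 10 volumes,
# detrend, regress tissue + Friston-24 motion confounds, band-pass
# 0.04-0.07 Hz, and apply the Jenkinson FD > 0.2 mm exclusion rule.

suppressPackageStartupMessages(library(lcsync))
dir.create("results/preproc", recursive = TRUE, showWarnings = FALSE)
set.seed(3)

for (state in c("off", "on")) {
  raw <- read_ts_tsv(sprintf("results/inputs/bold_%s.tsv", state),
                     sampling_interval = 2)
  # plausible slow drifts: small translations (mm) and rotations (rad)
  motion <- cbind(matrix(cumsum(rnorm(205 * 3, sd = 0.005)), 205, 3),
                  matrix(cumsum(rnorm(205 * 3, sd = 5e-5)), 205, 3))
  confounds <- matrix(rnorm(205 * 2), 205, 2)  # WM + CSF stand-ins
  res <- preprocess_bold(raw, confounds = confounds, motion = motion,
                         drop = 10, band = c(0.04, 0.07))
  write_ts_tsv(res$ts, sprintf("results/preproc/clean_%s.tsv", state))
  jsonlite::write_json(res$log,
                       sprintf("results/preproc/log_%s.json", state),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d -> %d volumes, confound rank %d, mean FD %.4f mm, excluded: %s\n",
              state, ncol(raw$values), ncol(res$ts$values),
              res$log$confound_rank, res$log$fd_summary, res$log$excluded))
}
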