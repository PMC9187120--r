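#!/usr/bin/env Rscript
# Stage 1: generate the Novice and Expert synthetic cohorts.
#
# Writes session directories plus the ground-truth unit tables under
# results/analysis/. Both cohorts share every generator parameter except
# the evoked-template amplitude set, which follows the published group
# means, so downstream stages can be checked against known truth.

suppressPackageStartupMessages(library(spikecohort))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20220531

for (grp in c("Novice", "Expert")) {
  cfg <- sim_config(n_units = c(RS = 12, FS = 6), group = grp,
                    seed = seed + (grp == "Expert"))
  g <- generate_session(cfg)
  save_session(g$session, file.path(out, paste0("session_",
                                                tolower(grp))))
  utils::write.csv(g$truth$units,
                   file.path(out, paste0("truth_", tolower(grp), ".csv")),
                   row.names = FALSE)
  message(sprintf("%s cohort: %d units, %d trials (%d whisker)",
                  grp, nrow(g$session$units), nrow(g$session$trials),
                  sum(!is.na(g$session$trials$whisker_onset_s))))
}
message("sessions written under ", out)
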