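#!/usr/bin/env Rscript
# Stage 2: spike-width measurement, RS/FS classification and baseline
# rates for both cohorts.
#
# Reads the stage-1 session directories, measures widths on the
# largest-amplitude-site waveforms, classifies units (FS < 0.26 ms,
# RS > 0.34 ms), fits the log-normal baseline-rate distribution per class
# and reports classification accuracy against ground truth.

suppressPackageStartupMessages(library(spikecohort))

out <- "results/analysis"
rows <- list()
for (grp in c("novice", "expert")) {
  s <- load_session(file.path(out, paste0("session_", grp)))
  s <- classify_session_units(s)
  truth <- utils::read.csv(file.path(out, paste0("truth_", grp, ".csv")))
  acc <- mean(s$units$cell_class ==
              truth$cell_class[match(s$units$unit_id, truth$unit_id)])
  u <- s$units; u$group <- grp
  rows[[grp]] <- u
  message(sprintf("%s: %d RS / %d FS / %d excluded; class accuracy %.1f%%",
                  grp, sum(u$cell_class == "RS"), sum(u$cell_class == "FS"),
                  sum(u$cell_class == "excluded"), 100 * acc))
  for (cc in c("RS", "FS")) {
    fit <- fit_lognormal_rates(u$baseline_rate_hz[u$cell_class == cc])
    message(sprintf("  %s baseline rates: mu_log %.2f, sigma_log %.2f (n=%d)",
                    cc, fit$mu_log, fit$sigma_log, fit$n_units))
  }
  save_session(s, file.path(out, paste0("session_", grp)))
}
units <- do.call(rbind, rows)
utils::write.csv(units, file.path(out, "units_classified.csv"),
                 row.names = FALSE)
message("wrote ", file.path(out, "units_classified.csv"))
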