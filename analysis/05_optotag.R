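#!/usr/bin/env Rscript
# Stage 5: opto-tagging on a synthetic light-stimulation session.
#
# Generates a session with 600-ms light trains in which ground-truth
# GABAergic (FS) units respond with short-latency, low-jitter first
# spikes, then recovers per-unit OMI, fidelity, latency, jitter and the
# tag decision (fidelity > 20%, latency < 4.5 ms, jitter < 2 ms).

suppressPackageStartupMessages(library(spikecohort))

out <- "results/analysis"
og <- generate_opto_session(sim_config(n_units = c(RS = 10, FS = 6),
                                       seed = 20220535))
tm <- session_tag_metrics(og$session, n_perm = 1000, seed = 5)
truth <- og$truth$units$tagged[match(tm$unit_id, og$truth$units$unit_id)]
tm$true_tagged <- truth
utils::write.csv(tm, file.path(out, "tag_metrics.csv"), row.names = FALSE)

message(sprintf("tagged %d/%d FS units and %d/%d RS units (truth: all FS)",
                sum(tm$tagged[tm$cell_class == "FS"]),
                sum(tm$cell_class == "FS"),
                sum(tm$tagged[tm$cell_class == "RS"]),
                sum(tm$cell_class == "RS")))
message(sprintf("tag recovery %.1f%%; mean OMI: FS %+.2f, RS %+.2f",
                100 * mean(tm$tagged == truth),
                mean(tm$omi[tm$cell_class == "FS"]),
                mean(tm$omi[tm$cell_class == "RS"])))
message("wrote ", file.path(out, "tag_metrics.csv"))
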