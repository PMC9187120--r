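#!/usr/bin/env Rscript
# Stage 4: half-maximum response latencies.
#
# Responsive units (permutation p < 0.05, post- vs pre-stimulus window)
# get a latency: the first time the baseline-subtracted smoothed PSTH
# reaches half of its in-window extremum. wS1/wS2 use the 100-ms window
# with a 5-ms kernel; all other areas the 200-ms window with 10 ms.

suppressPackageStartupMessages(library(spikecohort))

out <- "results/analysis"
rows <- list()
for (grp in c("novice", "expert")) {
  s <- load_session(file.path(out, paste0("session_", grp)))
  l <- session_latencies(s, n_perm = 1000, seed = 4)
  l$group <- grp
  rows[[grp]] <- l
  r <- l[l$responsive, ]
  message(sprintf("%s: %d/%d responsive units", grp, nrow(r), nrow(l)))
  med <- aggregate(latency_ms ~ area, r, median)
  for (i in seq_len(nrow(med)))
    message(sprintf("  %s median latency %.1f ms", med$area[i],
                    med$latency_ms[i]))
}
lat <- do.call(rbind, rows)
utils::write.csv(lat, file.path(out, "latencies.csv"), row.names = FALSE)
message("wrote ", file.path(out, "latencies.csv"))
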