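#!/usr/bin/env Rscript
# Stage 7: learning modulation index and E-I balance map.
#
# Grand-average evoked deltas per area x class in each cohort, the LMI
# (normalized Expert - Novice difference) and the per-area E-I balance
# (LMI_RS - LMI_FS). With the default generator amplitudes the signs
# reproduce the published pattern: opposite RS/FS changes in wM1 and
# wM2, congruent changes in ALM and tjM1.

suppressPackageStartupMessages(library(spikecohort))

out <- "results/analysis"
resp <- utils::read.csv(file.path(out, "evoked_responses.csv"))
lt <- lmi_table(resp[resp$group == "novice", ],
                resp[resp$group == "expert", ])
utils::write.csv(lt$lmi, file.path(out, "lmi.csv"), row.names = FALSE)
utils::write.csv(lt$ei, file.path(out, "ei_balance.csv"),
                 row.names = FALSE)

for (i in seq_len(nrow(lt$lmi)))
  message(sprintf("%-4s %s: dAP %+.2f -> %+.2f Hz, LMI %+.2f",
                  lt$lmi$area[i], lt$lmi$cell_class[i],
                  lt$lmi$delta_ap_novice[i], lt$lmi$delta_ap_expert[i],
                  lt$lmi$lmi[i]))
for (i in seq_len(nrow(lt$ei)))
  message(sprintf("%-4s E-I balance index %+.2f", lt$ei$area[i],
                  lt$ei$ei_lmi[i]))
message("wrote lmi.csv, ei_balance.csv")
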