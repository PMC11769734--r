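#!/usr/bin/env Rscript
# bp -> mp patient-level PI-RADS flow accounting: the 4x4 transition
# table over categories {<=2, 3, 4, 5}, the concordant fraction, and the
# csPCa prevalence inside each transition cell (upgrades that found
# cancer vs upgrades that added false positives).

library(pairedmrmc)

study <- load_study("results/study/readings.csv",
                    "results/study/cases.csv",
                    "results/study/readers.csv")

fl <- concordance_flow(study)
print(fl)

up34 <- fl$counts["3", "4"]
message(sprintf("PI-RADS 3 -> 4 upgrades: %d (%s%% of reads), csPCa fraction %.2f",
                up34, as_percent(up34 / fl$total),
                fl$cs_fraction["3", "4"]))

flow_df <- as.data.frame(as.table(fl$counts), stringsAsFactors = FALSE)
names(flow_df) <- c("bp_category", "mp_category", "n")
flow_df$cs_fraction <- round(as.vector(fl$cs_fraction), 3)
write.csv(flow_df, "results/flow_table.csv", row.names = FALSE)
message("wrote results/flow_table.csv")
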