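#!/usr/bin/env Rscript
# Decision curve analysis of the six biopsy pathways (each modality at
# each positivity rule) against treat-all/treat-none over threshold
# probabilities 5-30%, the net reduction in interventions, and the
# examinations-per-additional-diagnosis trade-off at the guideline 10%
# threshold.

library(pairedmrmc)

study <- load_study("results/study/readings.csv",
                    "results/study/cases.csv",
                    "results/study/readers.csv")

dc <- decision_curve(study)
out <- dc
out$nb <- round(out$nb, 4)
out$net_reduction <- round(out$net_reduction, 2)
write.csv(out, "results/decision_curves.csv", row.names = FALSE)

at10 <- dc[abs(dc$p_t - 0.10) < 1e-9, ]
at10 <- at10[order(-at10$nb), ]
message("net benefit at the 10% threshold:")
for (i in seq_len(nrow(at10)))
  message(sprintf("  %-10s %.4f", at10$strategy[i], at10$nb[i]))

gap <- at10$nb[at10$strategy == "mp_p3"] - at10$nb[at10$strategy == "bp_p3"]
message(sprintf(
  "mp vs bp at PI-RADS >=3, 10%% threshold: delta NB = %.4f -> %s exams per additional diagnosis",
  gap, format(round(exams_per_additional_case(gap)))))
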