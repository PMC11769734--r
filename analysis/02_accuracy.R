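#!/usr/bin/env Rscript
# Per-reader diagnostic accuracy under both modalities: empirical AUROC
# from the 0-100 suspicion scores, and sensitivity/specificity at the
# three biopsy-triggering rules (PI-RADS >=3; PI-RADS >=4 or 3 with
# PSAd >= 0.15; PI-RADS >=4). One CSV per metric/rule, readers as rows.

library(pairedmrmc)

study <- load_study("results/study/readings.csv",
                    "results/study/cases.csv",
                    "results/study/readers.csv")
dir.create("results/accuracy", showWarnings = FALSE, recursive = TRUE)

wide <- function(tab) {
  out <- reshape(tab[c("reader_id", "block_id", "modality", "value")],
                 idvar = c("reader_id", "block_id"),
                 timevar = "modality", direction = "wide")
  names(out) <- sub("value.", "", names(out), fixed = TRUE)
  out[order(out$reader_id), ]
}

auroc <- per_reader_metric_table(study, "auroc")
write.csv(wide(auroc), "results/accuracy/auroc.csv", row.names = FALSE)
message(sprintf("AUROC: bp %.3f, mp %.3f (means over %d readers)",
                mean(auroc$value[auroc$modality == "bp"]),
                mean(auroc$value[auroc$modality == "mp"]),
                nrow(study$readers)))

for (r in c("p3", "p4psad", "p4")) {
  rule <- positivity_rule(r)
  for (m in c("sensitivity", "specificity")) {
    tab <- per_reader_metric_table(study, m, rule)
    write.csv(wide(tab), sprintf("results/accuracy/%s_%s.csv", m, r),
              row.names = FALSE)
    message(sprintf("%s at %s: bp %.3f, mp %.3f", m, r,
                    mean(tab$value[tab$modality == "bp"]),
                    mean(tab$value[tab$modality == "mp"])))
  }
}
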