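#!/usr/bin/env Rscript
# Stage 2 — cost every hospital stay and compare cumulative costs between
# arms (cost-minimisation view): adjusted-DRG costing of the initial stay
# (micro-costed theatre cost + LOS-weighted daily cost), gross DRG costing
# of re-hospitalisations, flat tariff for rehabilitation stays.
suppressPackageStartupMessages(library(thoracoCUA))

patients <- read.csv("results/sim/patients.csv", stringsAsFactors = FALSE)
stays <- read.csv("results/sim/stays.csv", stringsAsFactors = FALSE)

costed <- cost_stays(stays, patients)
costs <- cumulative_costs(patients, costed)
write.csv(costed, "results/costed_stays.csv", row.names = FALSE)
write.csv(costs, "results/cumulative_costs.csv", row.names = FALSE)

cat("stays costed:", sum(!is.na(costed$cost)), "of", nrow(costed), "\n")
for (h in c("cost_d30", "cost_m3")) {
  m <- tapply(costs[[h]], costs$arm, mean)
  d <- mean_difference(costs[[h]][costs$arm == "VATS"],
                       costs[[h]][costs$arm == "THORACOTOMY"])
  cat(sprintf("%s: VATS %.0f vs thoracotomy %.0f EUR, difference %.0f (95%% CI %.0f to %.0f, p = %.3f)\n",
              h, m["VATS"], m["THORACOTOMY"], d$difference, d$ci_low,
              d$ci_high, d$p_value))
}
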