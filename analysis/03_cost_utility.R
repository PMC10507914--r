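#!/usr/bin/env Rscript
# Stage 3 — complete-case cost-utility analysis: interval-weighted QALYs,
# exclusion cascade, ICER point estimate, 10,000-replicate arm-stratified
# bootstrap, cost-utility plane and acceptability curve.
suppressPackageStartupMessages(library(thoracoCUA))

patients <- read.csv("results/sim/patients.csv", stringsAsFactors = FALSE)
observations <- read.csv("results/sim/eq5d_observations.csv",
                         stringsAsFactors = FALSE)
costs <- read.csv("results/cumulative_costs.csv", stringsAsFactors = FALSE)

for (h in c("d30", "m3")) {
  q <- compute_qalys(observations, h)
  casc <- apply_cua_exclusions(patients, q, h,
                               qalys_d30 = compute_qalys(observations, "d30"))
  cat("\n==", h, "horizon ==\n")
  print(casc$counts)
  out <- ce_outcomes(patients, costs, q, h, included = casc$included)
  dc <- mean_difference(out$cost[out$arm == "VATS"],
                        out$cost[out$arm == "THORACOTOMY"])
  de <- mean_difference(out$effect[out$arm == "VATS"],
                        out$effect[out$arm == "THORACOTOMY"])
  ic <- icer(dc$difference, de$difference)
  cat(sprintf("delta cost %.0f EUR, delta QALY %.4f -> ICER %s EUR/QALY (%s)\n",
              dc$difference, de$difference, icer_reported(ic), ic$quadrant))
  bt <- bootstrap_ce(out, B = 10000, seed = 42 + match(h, c("d30", "m3")))
  ci <- icer_ci(bt)
  cat(sprintf("bootstrap mean ICER %.0f (95%% CI %.0f to %.0f), NE share %.2f%%\n",
              ci$mean_icer, ci$ci_low, ci$ci_high,
              100 * quadrant_proportions(bt)[["NE"]]))
  curve <- ceac(bt)
  cat(sprintf("P(cost-effective at 25,000 EUR/QALY) = %.0f%%\n",
              100 * curve$probability[curve$wtp == 25000]))
  write.csv(bt$replicates, sprintf("results/cu_plane_%s.csv", h),
            row.names = FALSE)
  write.csv(curve, sprintf("results/ceac_%s.csv", h), row.names = FALSE)
}
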