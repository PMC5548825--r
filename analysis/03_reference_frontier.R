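#!/usr/bin/env Rscript
# Step 3: incremental analysis on the published per-patient means.
#
# The published evaluation reports per-patient means for the five strategies
# under three settings (NHS perspective, societal perspective, societal for a
# 25-year-old cohort). Feeding those printed means straight into the frontier
# operation reproduces the published dominance classifications and ICER
# ladders; this is the package's direct quantitative contact with the source
# results and is independent of the generated parameter world.

suppressMessages(library(cllcea))
dir.create("results", showWarnings = FALSE)

for (persp in c("nhs", "societal", "societal_age25")) {
  tab <- reference_results(persp)
  for (eff in c("ly", "qaly")) {
    fr <- frontier_from_table(tab, eff)
    scale <- if (eff == "ly") "CEA" else "CUA"
    cat(sprintf("\n=== %s, %s ===\n", persp, scale))
    print(fr)
    cat(sprintf("optimal at 20k/30k/50k: %s / %s / %s\n",
                fr$optimal_at(20000), fr$optimal_at(30000), fr$optimal_at(50000)))
    write.csv(fr$table,
              sprintf("results/reference_frontier_%s_%s.csv", persp, eff),
              row.names = FALSE)
  }
}
cat("\nwrote results/reference_frontier_*.csv\n")
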