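#!/usr/bin/env Rscript
# Step 6: societal costing perspective.
#
# Extends the NHS costing with friction-capped productivity losses, informal
# care and out-of-pocket costs, plus premature-mortality production losses
# (human-capital by default). Health outcomes are identical across
# perspectives; only costs move. Run for the 65-year-old base cohort and for
# 25-year-olds, where premature mortality dominates.

suppressMessages(library(cllcea))
dir.create("results", showWarnings = FALSE)

ps <- default_parameter_set()

for (age in c(65, 25)) {
  psa_ <- resolve(ps, list(starting_age_years = age))
  spec <- societal_spec(psa_, mortality_cost_approach = "human-capital")
  nhs <- evaluate_strategies(psa_)
  soc <- evaluate_strategies(psa_, societal = spec)
  cat(sprintf("\n=== societal perspective, starting age %d ===\n", age))
  cmp <- data.frame(strategy = nhs$strategy, nhs_cost = nhs$cost,
                    societal_cost = soc$cost,
                    increment = soc$cost - nhs$cost,
                    ly = soc$ly, qaly = soc$qaly)
  print(cmp, digits = 5)
  for (eff in c("ly", "qaly")) {
    fr <- frontier(soc, eff)
    cat(sprintf("%s optimal at 30k: %s\n", toupper(eff), fr$optimal_at(30000)))
    write.csv(fr$table,
              sprintf("results/societal_frontier_age%d_%s.csv", age, eff),
              row.names = FALSE)
  }
  write.csv(cmp, sprintf("results/societal_means_age%d.csv", age),
            row.names = FALSE)
}
cat("\nwrote results/societal_means_age{65,25}.csv and societal_frontier_*.csv\n")
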