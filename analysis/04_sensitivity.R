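#!/usr/bin/env Rscript
# Step 4: deterministic uncertainty analyses.
#
# (a) univariate sensitivity analysis: every non-fixed parameter varied to its
#     low/high value (+-50% of base unless a range is supplied), recording
#     whether the optimal strategy at 30,000 GBP/QALY changes;
# (b) the seven scenario analyses (ibrutinib price, list price, 40% responder
#     effect, starting ages 25/85, 10- and 50-year horizons, test
#     equalisation);
# (c) threshold analysis on the per-cycle ibrutinib drug cost.

suppressMessages(library(cllcea))
dir.create("results", showWarnings = FALSE)

ps <- default_parameter_set()

## (a) univariate SA over all non-fixed parameters plus the discount rate
sa <- univariate_sa(ps, effect = "qaly", lambda = 30000,
                    setting_ranges = list(
                      discount_rate_annual = c(0.0175, 0.0525),
                      responder_delta = c(0.10, 0.30)))
write.csv(sa, "results/univariate_sa.csv", row.names = FALSE)
changed <- sa[sa$changed, ]
cat(sprintf("univariate SA: %d variations, %d change the optimal strategy (base: %s)\n",
            nrow(sa), nrow(changed), attr(sa, "base_optimal")))
if (nrow(changed)) print(changed, digits = 4)

## (b) scenarios
scen_rows <- list()
for (id in 1:7) {
  runs <- if (id == 4) list(run_scenario(4, ps, age = 25),
                            run_scenario(4, ps, age = 85))
  else list(run_scenario(id, ps))
  for (sc in runs) {
    opt <- sc$base_case$optimal
    scen_rows[[length(scen_rows) + 1L]] <- data.frame(
      id = sc$id, description = sc$description,
      cea_optimal_30k = opt$cea_optimal[opt$threshold == 30000],
      cua_optimal_30k = opt$cua_optimal[opt$threshold == 30000],
      cua_optimal_50k = opt$cua_optimal[opt$threshold == 50000])
    cat(sprintf("scenario %d (%s): optimal at 30k CEA=%s CUA=%s; at 50k CUA=%s\n",
                sc$id, sc$description,
                scen_rows[[length(scen_rows)]]$cea_optimal_30k,
                scen_rows[[length(scen_rows)]]$cua_optimal_30k,
                scen_rows[[length(scen_rows)]]$cua_optimal_50k))
  }
}
write.csv(do.call(rbind, scen_rows), "results/scenarios.csv", row.names = FALSE)

## (c) threshold analysis: ibrutinib drug cost per cycle at which the
## first-line ibrutinib strategy becomes optimal
for (eff in c("ly", "qaly")) {
  thr <- threshold_search("ibr_drug_cost_cycle", c(500, 12000), ps, "Int1",
                          lambda = 30000, effect = eff, tol = 1)
  annual <- thr$value * 365.25 / 28
  cat(sprintf("threshold (%s): Int1 optimal below %.0f GBP/cycle (%.0f GBP/year), status %s\n",
              toupper(eff), thr$value, annual, thr$status))
}
cat("wrote results/univariate_sa.csv, results/scenarios.csv\n")
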