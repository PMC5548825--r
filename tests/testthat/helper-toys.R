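# Shared fixtures: minimal parameter sets, toy state spaces and independent
# oracles (path enumeration, lower convex hull).

# Minimal parameter set for toy models: background mortality only (zero by
# default so toys are exactly the matrices they specify).
tiny_params <- function(gompertz_a = 0, gompertz_b = 0, settings = list()) {
  tab <- data.frame(
    name = c("gompertz_a", "gompertz_b"),
    value = c(gompertz_a, gompertz_b),
    low = c(gompertz_a, gompertz_b), high = c(gompertz_a, gompertz_b),
    role = "rate", dist = "fixed", variance_source = "cv-default",
    stringsAsFactors = FALSE)
  parameter_set(tab, settings)
}

# Gompertz intercept giving an exact per-cycle other-cause probability p_oc
# at every age (with slope 0).
gompertz_a_for <- function(p_oc) -log(1 - p_oc) * 365.25 / 28

# Two-state toy: alive -> dead at probability p per cycle.
two_state_space <- function(p = 0.1) {
  T <- matrix(c(1 - p, p,
                0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("alive", "dead"), c("alive", "dead")))
  manual_state_space(T, entry = c(1, 0), roles = c("remission", "death-cll"))
}

# Independent brute-force oracle: enumerate every individual path and
# accumulate per-cycle occupancy. Tfun(cycle) must return the full transition
# matrix applied between `cycle` and `cycle + 1`.
brute_force_occupancy <- function(Tfun, entry, n_cycles) {
  n <- length(entry)
  occ <- matrix(0, n_cycles + 1L, n)
  rec <- function(state, cycle, prob) {
    occ[cycle + 1L, state] <<- occ[cycle + 1L, state] + prob
    if (cycle == n_cycles) return(invisible())
    row <- Tfun(cycle)[state, ]
    for (s2 in which(row > 0)) rec(s2, cycle + 1L, prob * row[s2])
  }
  for (s in which(entry > 0)) rec(s, 0L, entry[s])
  occ
}

# Independent cost-effectiveness frontier oracle: Andrew's monotone-chain
# lower convex hull of (effect, cost), trimmed to the nonnegative-slope
# section starting at the cheapest point.
hull_frontier_oracle <- function(df) {
  o <- order(df$effect, df$cost)
  E <- df$effect[o]; C <- df$cost[o]; S <- df$strategy[o]
  hull <- integer()
  cross <- function(i, j, k)
    (E[j] - E[i]) * (C[k] - C[i]) - (C[j] - C[i]) * (E[k] - E[i])
  for (k in seq_along(E)) {
    while (length(hull) >= 2 &&
           cross(hull[length(hull) - 1L], hull[length(hull)], k) <= 0)
      hull <- hull[-length(hull)]
    hull <- c(hull, k)
  }
  costs <- C[hull]
  start <- which(costs == min(costs))
  start <- start[length(start)]          # cheapest; ties -> most effective
  S[hull[start:length(hull)]]
}

# Strategy evaluation cache for the deterministic default set (several test
# files reuse these).
default_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- evaluate_strategies(default_parameter_set())
    cache
  }
})
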