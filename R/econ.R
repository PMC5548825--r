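## Economic evaluation: per-strategy discounted means and the incremental
## analysis with strict and extended dominance.

#' Evaluate a cohort trace
#'
#' Accumulates discounted mean cost, life-years and QALYs per patient.
#' Half-cycle-corrected occupancies are used for per-cycle accruals (for costs
#' and/or outcomes according to the settings); one-off costs (tests on entry
#' into a line, and societal premature-mortality losses when a societal
#' specification is attached) are charged on state arrival at the arrival
#' cycle's discount factor.
#'
#' @param trace A `cll_cohort_trace`.
#' @param params The `cll_parameter_set` the trace was run under.
#' @param societal Optional `cll_societal_spec` (see [societal_spec()]); when
#'   supplied, per-cycle societal increments (friction-capped productivity,
#'   informal care, out-of-pocket) and premature-mortality losses are added to
#'   costs. Health outcomes are unaffected.
#' @return A one-row data frame (class `cll_econ_result`): `strategy`, `cost`,
#'   `ly`, `qaly`, plus undiscounted `ly_undisc`, `qaly_undisc`, `cost_undisc`.
#' @export
evaluate <- function(trace, params, societal = NULL) {
  stopifnot(inherits(trace, "cll_cohort_trace"))
  societal <- societal %||% params$societal
  space <- trace$space
  st <- params$settings
  N <- trace$n_cycles
  dt <- cycle_years(st$cycle_length_days)
  disc <- discount_factor(0:(N - 1), st$discount_rate_annual, st$cycle_length_days)
  eff <- half_cycle_correct(trace)
  raw <- trace$occupancy[seq_len(N), , drop = FALSE]
  occ_cost <- if (isTRUE(st$half_cycle_costs)) eff else raw
  occ_out <- if (isTRUE(st$half_cycle_outcomes)) eff else raw

  costs <- space$states$cost
  utils_ <- space$states$utility
  alive <- as.numeric(space$alive)
  if (!is.null(societal)) {
    stopifnot(inherits(societal, "cll_societal_spec"))
    ages <- trace$starting_age_years + (0:(N - 1)) * dt
    soc <- societal_cycle_costs(space, societal, ages)   # N x n matrix
    cyc_cost <- rowSums(occ_cost * (soc +
                                      matrix(costs, N, length(costs), byrow = TRUE)))
  } else {
    cyc_cost <- as.numeric(occ_cost %*% costs)
  }
  cost_d <- sum(disc * cyc_cost)
  cost_u <- sum(cyc_cost)

  ## one-off costs on arrival (cycle 0 arrivals are the entry distribution)
  arr <- trace$arrivals
  entry_costs <- space$states$entry_cost
  if (any(entry_costs > 0)) {
    disc_arr <- discount_factor(0:N, st$discount_rate_annual, st$cycle_length_days)
    oneoff <- as.numeric(arr %*% entry_costs)
    cost_d <- cost_d + sum(disc_arr * oneoff)
    cost_u <- cost_u + sum(oneoff)
  }
  if (!is.null(societal)) {
    mort <- societal_event_costs(trace, societal)   # length N+1 per-arrival-cycle losses
    disc_arr <- discount_factor(0:N, st$discount_rate_annual, st$cycle_length_days)
    cost_d <- cost_d + sum(disc_arr * mort)
    cost_u <- cost_u + sum(mort)
  }

  ly_cyc <- as.numeric(occ_out %*% alive) * dt
  qaly_cyc <- as.numeric(occ_out %*% (utils_ * alive)) * dt
  out <- data.frame(strategy = space$strategy,
                    cost = cost_d, ly = sum(disc * ly_cyc),
                    qaly = sum(disc * qaly_cyc),
                    cost_undisc = cost_u, ly_undisc = sum(ly_cyc),
                    qaly_undisc = sum(qaly_cyc),
                    stringsAsFactors = FALSE)
  class(out) <- c("cll_econ_result", class(out))
  out
}

#' Evaluate a set of strategies on a parameter set
#'
#' Builds, runs and evaluates each strategy.
#'
#' @param params A `cll_parameter_set`.
#' @param strategies Character vector of strategy names (default all five).
#' @param societal Optional `cll_societal_spec` for the societal perspective.
#' @param test_overrides Optional named list mapping strategy name to a
#'   `cll_test_spec` override (used by the test-equalisation scenario).
#' @return Data frame with one row per strategy (cost/ly/qaly, discounted and
#'   undiscounted).
#' @export
evaluate_strategies <- function(params, strategies = STRATEGY_NAMES,
                                societal = NULL, test_overrides = NULL) {
  rows <- lapply(strategies, function(nm) {
    strat <- build_strategy(nm, params, test_override = test_overrides[[nm]])
    space <- build_state_space(strat, params)
    evaluate(run_cohort(space, params), params, societal = societal)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Incremental cost-effectiveness ratio
#'
#' @param more_effective,less_effective One-row results (or lists) with
#'   `cost` and the chosen effect column.
#' @param effect Effect column: "ly" or "qaly".
#' @return (delta cost) / (delta effect), GBP per unit effect.
#' @export
icer <- function(more_effective, less_effective, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  de <- more_effective[[effect]] - less_effective[[effect]]
  if (de == 0) stop_named("ICER undefined: zero effect difference")
  (more_effective$cost - less_effective$cost) / de
}

#' Net monetary benefit
#'
#' @param result One-row result (or list) with `cost` and the effect column.
#' @param threshold Willingness to pay, GBP per unit effect (>= 0).
#' @param effect "ly" or "qaly".
#' @return threshold * effect - cost.
#' @export
nmb <- function(result, threshold, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  stopifnot(all(threshold >= 0))
  threshold * result[[effect]] - result$cost
}

#' Incremental analysis with strict and extended dominance
#'
#' Sorts strategies by ascending cost, marks strictly dominated strategies
#' (costlier and no more effective than some alternative; on exact cost/effect
#' ties the later-listed strategy is marked dominated), computes the ICER
#' ladder over the survivors, then iteratively removes extendedly dominated
#' strategies (ICER exceeding that of the next more-effective strategy,
#' recomputing the ladder after each removal) until the frontier's ICERs
#' strictly increase.
#'
#' @param results Data frame with columns `strategy`, `cost` and the effect
#'   column; one row per distinct strategy.
#' @param effect "ly" (cost-effectiveness) or "qaly" (cost-utility).
#' @return A list of class `cll_frontier`: `table` (input plus `label`,
#'   `icer_excl_dom`, `icer_excl_ext_dom`, sorted by cost), `dominated`,
#'   `extendedly_dominated`, `frontier` (final survivors, ascending cost) and
#'   `optimal_at(lambda)`.
#' @export
frontier <- function(results, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  df <- as.data.frame(results)[, c("strategy", "cost", effect)]
  names(df)[3] <- "effect"
  if (anyDuplicated(df$strategy)) stop_named("duplicate strategy names")
  if (nrow(df) < 1L) stop_named("frontier needs at least one strategy")
  df <- df[order(df$cost, df$effect), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)

  dominated <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    strictly <- (df$cost[i] > df$cost[j] && df$effect[i] <= df$effect[j]) ||
      (df$cost[i] == df$cost[j] && df$effect[i] < df$effect[j]) ||
      (df$cost[i] == df$cost[j] && df$effect[i] == df$effect[j] && j < i)
    if (strictly && !dominated[j]) dominated[i] <- TRUE
  }

  ladder <- function(active) {
    ic <- rep(NA_real_, n)
    act <- which(active)
    if (length(act) > 1L)
      for (k in 2:length(act)) {
        de <- df$effect[act[k]] - df$effect[act[k - 1]]
        ic[act[k]] <- if (de == 0) Inf else
          (df$cost[act[k]] - df$cost[act[k - 1]]) / de
      }
    ic
  }

  active <- !dominated
  icer_excl_dom <- ladder(active)
  ext <- rep(FALSE, n)
  repeat {
    ic <- ladder(active)
    act <- which(active)
    viol <- NULL
    if (length(act) > 2L)
      for (k in 2:(length(act) - 1L))
        if (ic[act[k]] >= ic[act[k + 1L]]) { viol <- act[k]; break }
    if (is.null(viol)) break
    ext[viol] <- TRUE
    active[viol] <- FALSE
  }
  icer_final <- ladder(active)

  df$label <- ifelse(dominated, "DOM", ifelse(ext, "EXT.DOM", ""))
  df$icer_excl_dom <- icer_excl_dom
  df$icer_excl_ext_dom <- ifelse(active, icer_final, NA_real_)

  surv <- df$strategy[active]
  surv_eff <- df$effect[active]
  surv_icer <- icer_final[active]
  optimal_at <- function(lambda) {
    ok <- which(is.na(surv_icer) | surv_icer <= lambda)
    surv[ok[which.max(surv_eff[ok])]]
  }
  structure(list(table = df, effect = effect,
                 dominated = df$strategy[dominated],
                 extendedly_dominated = df$strategy[ext],
                 frontier = surv, optimal_at = optimal_at),
            class = "cll_frontier")
}

#' @export
print.cll_frontier <- function(x, ...) {
  cat(sprintf("<cll_frontier (%s)>\n", x$effect))
  print(x$table, digits = 6)
  invisible(x)
}

#' Run the incremental analysis on supplied per-strategy means
#'
#' Drives [frontier()] directly from a table of (strategy, effect, cost)
#' means, e.g. published per-patient results: row order is irrelevant
#' (strategies are sorted by cost).
#'
#' @param x Data frame with columns `strategy`, `cost` and an effect column,
#'   or the path to such a CSV.
#' @param effect Name of the effect column in `x` ("ly" or "qaly").
#' @return A `cll_frontier`.
#' @export
frontier_from_table <- function(x, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("strategy", "cost", effect)
  if (!all(need %in% names(x)))
    stop_named("table must have columns: %s", paste(need, collapse = ", "))
  if (!all(vapply(x[c("cost", effect)], is.numeric, TRUE)))
    stop_named("cost and effect columns must be numeric")
  frontier(x[, need], effect = effect)
}

#' Base-case report: per-strategy means and both ICER ladders
#'
#' Evaluates all requested strategies and returns the cost-effectiveness
#' (life-year) and cost-utility (QALY) incremental analyses, plus the optimal
#' strategy at each configured willingness-to-pay threshold.
#'
#' @param params A `cll_parameter_set`.
#' @param strategies Strategies to include (default all five).
#' @param societal Optional `cll_societal_spec`.
#' @return List with `results` (per-strategy means), `cea` and `cua`
#'   (`cll_frontier` objects) and `optimal` (data frame threshold x scale).
#' @export
run_base_case <- function(params, strategies = STRATEGY_NAMES, societal = NULL) {
  res <- evaluate_strategies(params, strategies, societal = societal)
  fr_ly <- frontier(res, effect = "ly")
  fr_q <- frontier(res, effect = "qaly")
  lam <- params$settings$thresholds_gbp
  opt <- data.frame(
    threshold = lam,
    cea_optimal = vapply(lam, fr_ly$optimal_at, ""),
    cua_optimal = vapply(lam, fr_q$optimal_at, ""),
    stringsAsFactors = FALSE)
  list(results = res, cea = fr_ly, cua = fr_q, optimal = opt)
}
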