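## Uncertainty analyses: univariate sensitivity analysis, the seven scenario
## analyses, threshold searches, and probabilistic sensitivity analysis with
## cost-effectiveness acceptability curves.

#' Beta distribution parameters by the method of moments
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with sd^2 < mean (1 - mean).
#' @return Named vector c(alpha, beta).
#' @export
beta_params <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop_named("beta mean must lie in (0, 1)")
  if (sd <= 0 || sd^2 >= mean * (1 - mean))
    stop_named("infeasible sd for a beta distribution (sd^2 must be < mean(1-mean))")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution parameters by the method of moments
#'
#' shape = (mean/sd)^2, scale = sd^2/mean; at the default coefficient of
#' variation of 0.10 the shape is 100 regardless of the mean.
#'
#' @param mean Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return Named vector c(shape, scale).
#' @export
gamma_params <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop_named("gamma mean and sd must be > 0")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

# Per-parameter sampling sd: reported ranges are read as 95% intervals,
# otherwise the default coefficient of variation applies.
.param_sd <- function(tab, cv_default) {
  sd <- cv_default * abs(tab$value)
  rep_i <- tab$variance_source == "reported" & tab$high > tab$low
  sd[rep_i] <- (tab$high[rep_i] - tab$low[rep_i]) / (2 * 1.96)
  sd
}

# Event probabilities that share a transition row and must jointly leave room
# for the persistence mass.
.row_groups <- function(names) {
  groups <- list()
  for (trt in c("fcr", "br", "ofa"))
    for (st in c("resp", "mut", "unknown"))
      groups[[paste(trt, st)]] <- sprintf(c("p_nonresp_%s_%s", "p_death_%s_%s"), trt, st)
  groups[["ibr"]] <- c("p_nonresp_ibr", "p_death_ibr")
  Filter(function(g) all(g %in% names), groups)
}

#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter from its assigned distribution (beta for
#' probabilities/utilities/proportions, gamma for costs and rates; method-of-
#' moments parameterisation with sd = CV x mean when no variance is reported)
#' and evaluates all strategies deterministically on each draw. Event
#' probabilities sharing a transition row are renormalised if their sampled
#' sum exceeds 0.95 (logged on the result). Seeded and bit-reproducible.
#'
#' @param base A `cll_parameter_set`.
#' @param n_sims Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param strategies Strategies to evaluate.
#' @param societal Optional `cll_societal_spec`.
#' @return A `cll_psa`: `draws` (data frame sim x strategy results), `seed`,
#'   `n_sims`, `n_renormalised`.
#' @export
sample_psa <- function(base, n_sims = 1000L, seed = 1L,
                       strategies = STRATEGY_NAMES, societal = NULL) {
  stopifnot(inherits(base, "cll_parameter_set"), n_sims >= 1)
  tab <- base$table
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)

  n_par <- nrow(tab)
  sd <- .param_sd(tab, base$settings$cv_default)
  draws <- matrix(rep(tab$value, each = n_sims), n_sims, n_par)
  for (i in seq_len(n_par)) {
    if (tab$dist[i] == "fixed" || sd[i] <= 0) next
    m <- tab$value[i]
    if (tab$dist[i] == "beta") {
      s <- min(sd[i], 0.95 * sqrt(m * (1 - m)))
      ab <- beta_params(m, s)
      draws[, i] <- stats::rbeta(n_sims, ab["alpha"], ab["beta"])
    } else {
      gp <- gamma_params(m, sd[i])
      draws[, i] <- stats::rgamma(n_sims, shape = gp["shape"], scale = gp["scale"])
    }
  }
  colnames(draws) <- tab$name

  groups <- .row_groups(tab$name)
  n_renorm <- 0L
  for (g in groups) {
    gi <- match(g, tab$name)
    tot <- rowSums(draws[, gi, drop = FALSE])
    bad <- tot > 0.95
    if (any(bad)) {
      n_renorm <- n_renorm + sum(bad)
      draws[bad, gi] <- draws[bad, gi, drop = FALSE] * (0.95 / tot[bad])
    }
  }

  res <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    tab_s <- tab
    tab_s$value <- draws[s, ]
    tab_s$low <- pmin(tab_s$low, tab_s$value)
    tab_s$high <- pmax(tab_s$high, tab_s$value)
    ps <- parameter_set(tab_s, base$settings, validate = FALSE)
    ps$societal <- base$societal
    r <- evaluate_strategies(ps, strategies, societal = societal)
    r$sim <- s
    res[[s]] <- r
  }
  structure(list(draws = do.call(rbind, res), seed = seed, n_sims = n_sims,
                 strategies = strategies, n_renormalised = n_renorm),
            class = "cll_psa")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability that each strategy
#' maximises net monetary benefit across the PSA draws; ties are split evenly,
#' so probabilities sum to 1 at every threshold.
#'
#' @param psa A `cll_psa` (or its `draws` data frame).
#' @param thresholds Threshold grid in GBP (default 0 to 100,000 by 2,500).
#' @param effect "ly" or "qaly".
#' @return A data frame (class `cll_ceac`) with column `threshold` and one
#'   probability column per strategy.
#' @export
ceac <- function(psa, thresholds = seq(0, 100000, by = 2500),
                 effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  draws <- if (inherits(psa, "cll_psa")) psa$draws else psa
  if (nrow(draws) == 0L) stop_named("empty PSA result")
  strategies <- unique(draws$strategy)
  sims <- sort(unique(draws$sim))
  C <- matrix(NA_real_, length(sims), length(strategies),
              dimnames = list(NULL, strategies))
  E <- C
  for (k in seq_along(strategies)) {
    d <- draws[draws$strategy == strategies[k], ]
    d <- d[order(d$sim), ]
    C[, k] <- d$cost
    E[, k] <- d[[effect]]
  }
  out <- matrix(0, length(thresholds), length(strategies),
                dimnames = list(NULL, strategies))
  for (t in seq_along(thresholds)) {
    nmb_m <- thresholds[t] * E - C
    best <- nmb_m == matrixStats_rowMaxs(nmb_m)
    wins <- best / rowSums(best)
    out[t, ] <- colMeans(wins)
  }
  res <- data.frame(threshold = thresholds, out, check.names = FALSE)
  class(res) <- c("cll_ceac", class(res))
  res
}

# rowMaxs without a matrixStats dependency.
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Univariate sensitivity analysis
#'
#' Varies each parameter one at a time to its low and high value (+-50% of
#' base by default, truncated to respect invariants at generation time) and
#' records whether the optimal strategy at the decision threshold changes.
#' Scalar settings can be varied too (e.g. the discount rate).
#'
#' @param base A `cll_parameter_set`.
#' @param strategies Strategies to evaluate.
#' @param effect "ly" or "qaly".
#' @param lambda Decision threshold (default 30,000 GBP).
#' @param param_names Parameters to vary (default: all non-fixed parameters).
#' @param setting_ranges Optional named list of length-2 numeric vectors for
#'   settings, e.g. list(discount_rate_annual = c(0.0175, 0.0525)).
#' @return Data frame: parameter, side, value, optimal strategy, changed flag.
#' @export
univariate_sa <- function(base, strategies = STRATEGY_NAMES,
                          effect = c("qaly", "ly"), lambda = 30000,
                          param_names = NULL, setting_ranges = NULL) {
  effect <- match.arg(effect)
  tab <- base$table
  param_names <- param_names %||% tab$name[tab$dist != "fixed"]
  base_res <- evaluate_strategies(base, strategies)
  base_opt <- frontier(base_res, effect)$optimal_at(lambda)
  one <- function(label, overrides, value, side) {
    ps <- resolve(base, overrides)
    res <- evaluate_strategies(ps, strategies)
    opt <- frontier(res, effect)$optimal_at(lambda)
    data.frame(parameter = label, side = side, value = value,
               optimal = opt, changed = !identical(opt, base_opt),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nm in param_names) {
    i <- match(nm, tab$name)
    if (is.na(i)) stop_named("unknown parameter '%s'", nm)
    for (side in c("low", "high")) {
      v <- tab[[side]][i]
      rows[[paste(nm, side)]] <- one(nm, stats::setNames(list(v), nm), v, side)
    }
  }
  for (nm in names(setting_ranges)) {
    rng <- setting_ranges[[nm]]
    for (k in 1:2)
      rows[[paste(nm, k)]] <- one(nm, stats::setNames(list(rng[k]), nm),
                                  rng[k], c("low", "high")[k])
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  attr(out, "base_optimal") <- base_opt
  out
}

#' Run a predefined scenario analysis
#'
#' Built-in scenarios: 1 ibrutinib drug cost x 0.25 (575 GBP per cycle);
#' 2 ibrutinib at the 56,000 GBP/year list price (x 56/30); 3 responder
#' effect raised from 20% to 40%; 4 starting age 25 or 85; 5 10-year horizon;
#' 6 50-year horizon; 7 genomic test cost and accuracy equalised to the
#' genetic test. Results are reported at all configured thresholds.
#'
#' @param id Scenario id 1..7.
#' @param base A `cll_parameter_set`.
#' @param strategies Strategies to evaluate.
#' @param age For scenario 4: starting age (default 25).
#' @param ibrutinib_multiplier For scenario 1: drug-cost multiplier (default 0.25).
#' @return List: `id`, `description`, `params` (modified set), `base_case`
#'   (see [run_base_case()]).
#' @export
run_scenario <- function(id, base, strategies = STRATEGY_NAMES, age = 25,
                         ibrutinib_multiplier = 0.25) {
  stopifnot(id %in% 1:7)
  overrides <- list()
  test_overrides <- NULL
  desc <- ""
  if (id == 1) {
    overrides$ibr_drug_cost_cycle <- param_value(base, "ibr_drug_cost_cycle") *
      ibrutinib_multiplier
    desc <- sprintf("ibrutinib drug cost x %.2f (%.0f GBP/cycle)",
                    ibrutinib_multiplier, overrides$ibr_drug_cost_cycle)
  } else if (id == 2) {
    overrides$ibr_drug_cost_cycle <- param_value(base, "ibr_drug_cost_cycle") * 56 / 30
    desc <- "ibrutinib at the 56,000 GBP/year list price"
  } else if (id == 3) {
    overrides$responder_delta <- 0.40
    desc <- "responder effect 40% (from 20%)"
  } else if (id == 4) {
    overrides$starting_age_years <- age
    desc <- sprintf("starting age %g", age)
  } else if (id == 5) {
    overrides$horizon_years <- 10
    desc <- "10-year horizon"
  } else if (id == 6) {
    overrides$horizon_years <- 50
    desc <- "50-year horizon"
  } else if (id == 7) {
    desc <- "genomic test cost and accuracy equalised to the genetic test"
  }
  ps <- resolve(base, overrides)
  if (id == 7) {
    ts <- test_spec("genetic", ps)
    test_overrides <- list(Int1 = ts, Int2 = ts)
  }
  res <- evaluate_strategies(ps, strategies, test_overrides = test_overrides)
  fr_ly <- frontier(res, "ly")
  fr_q <- frontier(res, "qaly")
  lam <- ps$settings$thresholds_gbp
  list(id = id, description = desc, params = ps,
       base_case = list(results = res, cea = fr_ly, cua = fr_q,
                        optimal = data.frame(
                          threshold = lam,
                          cea_optimal = vapply(lam, fr_ly$optimal_at, ""),
                          cua_optimal = vapply(lam, fr_q$optimal_at, ""))))
}

#' Threshold search on a single parameter
#'
#' Bisection for the parameter value at which a target strategy becomes the
#' optimal choice at the decision threshold. The decision is assumed monotone
#' in the parameter over the bracket; this is verified at the bracket ends.
#'
#' @param param_name Parameter (or scalar setting) to vary.
#' @param bracket Length-2 numeric search bracket.
#' @param base A `cll_parameter_set`.
#' @param target_strategy Strategy that should become optimal.
#' @param lambda Decision threshold (default 30,000).
#' @param effect "ly" or "qaly".
#' @param tol Absolute tolerance on the parameter (default 1, i.e. 1 GBP).
#' @param strategies Strategies in the comparison.
#' @return List: `value` (critical parameter value), `status` ("ok",
#'   "target-optimal-throughout", "never-optimal"), `optimal_low`,
#'   `optimal_high` (optimal strategies at the bracket ends).
#' @export
threshold_search <- function(param_name, bracket, base, target_strategy,
                             lambda = 30000, effect = c("qaly", "ly"), tol = 1,
                             strategies = STRATEGY_NAMES) {
  effect <- match.arg(effect)
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  opt_at <- function(x) {
    ps <- resolve(base, stats::setNames(list(x), param_name))
    frontier(evaluate_strategies(ps, strategies), effect)$optimal_at(lambda)
  }
  o_lo <- opt_at(bracket[1])
  o_hi <- opt_at(bracket[2])
  hit_lo <- identical(o_lo, target_strategy)
  hit_hi <- identical(o_hi, target_strategy)
  if (hit_lo && hit_hi)
    return(list(value = bracket[1], status = "target-optimal-throughout",
                optimal_low = o_lo, optimal_high = o_hi))
  if (!hit_lo && !hit_hi)
    return(list(value = NA_real_, status = "never-optimal",
                optimal_low = o_lo, optimal_high = o_hi))
  lo <- bracket[1]; hi <- bracket[2]
  ## invariant: exactly one end satisfies the target
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(opt_at(mid), target_strategy) == hit_lo) lo <- mid else hi <- mid
  }
  crit <- if (hit_lo) lo else hi   # last value at which the target is optimal
  list(value = crit, status = "ok", optimal_low = o_lo, optimal_high = o_hi)
}
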