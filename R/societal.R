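## Societal costing extension: productivity losses (friction-cost approach for
## absenteeism), informal care and out-of-pocket costs, plus premature-
## mortality production losses. Costs only: health outcomes are identical to
## the NHS perspective.

#' Societal cost specification
#'
#' Bundles the societal unit costs from a parameter set. All components are
#' increments on top of NHS costs, so a zero specification reproduces the NHS
#' perspective exactly.
#'
#' @param params A `cll_parameter_set` carrying the `soc_*` parameters.
#' @param mortality_cost_approach "human-capital" (production lost from death
#'   to retirement age; default, needed for the young-cohort scenario where
#'   premature mortality dominates) or "friction" (losses limited to the
#'   friction period).
#' @return An object of class `cll_societal_spec`.
#' @export
societal_spec <- function(params, mortality_cost_approach = c("human-capital", "friction")) {
  mortality_cost_approach <- match.arg(mortality_cost_approach)
  pv <- function(n) param_value(params, n)
  structure(list(
    daily_wage = pv("soc_daily_wage"),
    friction_period_days = pv("soc_friction_period_days"),
    informal_care_unit_cost = pv("soc_informal_care_cost_hour"),
    retirement_age_years = pv("soc_retirement_age"),
    employment_rate_by_age = c("16-54" = pv("soc_emp_rate_16_54"),
                               "55-64" = pv("soc_emp_rate_55_64"),
                               "65+" = pv("soc_emp_rate_65plus")),
    informal_care_hours = c(treat = pv("soc_ic_hours_treat"),
                            bmt = pv("soc_ic_hours_bmt"),
                            rem = pv("soc_ic_hours_rem"),
                            bsc = pv("soc_ic_hours_bsc")),
    oop_per_cycle = c(treat = pv("soc_oop_treat"),
                      bmt = pv("soc_oop_bmt"),
                      rem = pv("soc_oop_rem"),
                      bsc = pv("soc_oop_bsc")),
    absence_days_remission = pv("soc_absence_days_rem"),
    mortality_cost_approach = mortality_cost_approach),
    class = "cll_societal_spec")
}

#' Zero societal specification (NHS perspective)
#' @return A `cll_societal_spec` with every component zero.
#' @export
zero_societal_spec <- function() {
  structure(list(
    daily_wage = 0, friction_period_days = 0, informal_care_unit_cost = 0,
    retirement_age_years = 65,
    employment_rate_by_age = c("16-54" = 0, "55-64" = 0, "65+" = 0),
    informal_care_hours = c(treat = 0, bmt = 0, rem = 0, bsc = 0),
    oop_per_cycle = c(treat = 0, bmt = 0, rem = 0, bsc = 0),
    absence_days_remission = 0,
    mortality_cost_approach = "human-capital"),
    class = "cll_societal_spec")
}

#' Age-band employment rate
#' @param age_years Age (vectorised).
#' @param spec A `cll_societal_spec`.
#' @return Employment rate in [0, 1]; zero from retirement age.
#' @export
employment_rate <- function(age_years, spec) {
  r <- spec$employment_rate_by_age
  out <- ifelse(age_years < 55, r[["16-54"]],
                ifelse(age_years < 65, r[["55-64"]], r[["65+"]]))
  ifelse(age_years >= spec$retirement_age_years, 0, out)
}

#' Friction-cost productivity loss for an absence
#'
#' daily_wage x employment_rate(age) x min(absence_days, friction_period):
#' losses accrue only until the worker is replaced.
#'
#' @param absence_days Days absent (>= 0).
#' @param age_years Age of the patient.
#' @param spec A `cll_societal_spec`.
#' @return Productivity cost in GBP.
#' @export
friction_productivity_cost <- function(absence_days, age_years, spec) {
  if (any(absence_days < 0)) stop_named("absence_days must be >= 0")
  spec$daily_wage * employment_rate(age_years, spec) *
    pmin(absence_days, spec$friction_period_days)
}

#' Premature-mortality production loss at a given age of death
#'
#' Human-capital: daily wage x employment rate summed over each year from the
#' age at death to retirement. Friction: losses limited to one friction
#' period. Zero at or beyond retirement age.
#'
#' @param age_years Age at death.
#' @param spec A `cll_societal_spec`.
#' @return Production loss in GBP.
#' @export
mortality_production_loss <- function(age_years, spec) {
  vapply(age_years, function(a) {
    if (a >= spec$retirement_age_years) return(0)
    if (spec$mortality_cost_approach == "friction")
      return(spec$daily_wage * employment_rate(a, spec) * spec$friction_period_days)
    years <- spec$retirement_age_years - a
    k <- seq_len(ceiling(years)) - 1L
    frac <- pmin(1, years - k)
    sum(spec$daily_wage * DAYS_PER_YEAR * employment_rate(a + k, spec) * frac)
  }, 0)
}

# Per-cycle societal increments for every state at every cycle age.
# Chemotherapy/BMT tunnel states accrue friction-capped absenteeism by tunnel
# index (the cap binds within the first ~friction/28 cycles of a line);
# remission accrues a small intermittent absence. Continuous-treatment
# (ibrutinib) and BSC episodes are charged one friction period on entry via
# societal_event_costs().
societal_cycle_costs <- function(space, spec, ages) {
  st <- space$states
  n <- nrow(st)
  N <- length(ages)
  grp <- rep(NA_character_, n)
  grp[st$role %in% "treatment-tunnel"] <- "treat"
  grp[st$role == "bmt-tunnel"] <- "bmt"
  grp[st$role %in% c("remission", "bmt-remission")] <- "rem"
  grp[st$role == "bsc"] <- "bsc"
  fixed <- ifelse(is.na(grp), 0,
                  spec$informal_care_hours[grp] * spec$informal_care_unit_cost +
                    spec$oop_per_cycle[grp])
  ## absence days per cycle by state (age-independent part)
  days <- numeric(n)
  tun <- which(st$role %in% c("treatment-tunnel", "bmt-tunnel") & !is.na(st$tunnel_index))
  days[tun] <- pmin(28, pmax(0, spec$friction_period_days - 28 * (st$tunnel_index[tun] - 1L)))
  days[st$role %in% c("remission", "bmt-remission")] <- spec$absence_days_remission
  emp <- employment_rate(ages, spec)                        # length N
  out <- matrix(fixed, N, n, byrow = TRUE)
  if (any(days > 0) && any(emp > 0))
    out <- out + (spec$daily_wage * emp) %o% days
  out
}

# Event-based societal costs per arrival cycle: premature CLL-mortality
# production losses, plus one friction period of absenteeism on entry into an
# open-ended illness episode (ibrutinib treatment or best supportive care).
societal_event_costs <- function(trace, spec) {
  space <- trace$space
  st <- space$states
  N <- trace$n_cycles
  dt <- cycle_years(trace$cycle_length_days)
  ages <- trace$starting_age_years + (0:N) * dt
  out <- numeric(N + 1L)
  death_idx <- which(st$role == "death-cll")
  if (length(death_idx)) {
    loss <- mortality_production_loss(ages, spec)
    out <- out + rowSums(trace$arrivals[, death_idx, drop = FALSE]) * loss
  }
  episode_idx <- which((st$treatment == "ibr" & st$role == "treatment-tunnel") |
                         st$role == "bsc")
  if (length(episode_idx) && spec$daily_wage > 0) {
    fr <- spec$daily_wage * employment_rate(ages, spec) * spec$friction_period_days
    out <- out + rowSums(trace$arrivals[, episode_idx, drop = FALSE]) * fr
  }
  out
}

#' Attach a societal costing specification to a parameter set
#'
#' Returns a parameter set whose evaluations include the societal increments
#' (per-cycle productivity/informal-care/out-of-pocket additions and
#' event-based premature-mortality and episode-absenteeism losses). Passing a
#' zero specification recovers the NHS perspective exactly.
#'
#' @param params A `cll_parameter_set`.
#' @param spec A `cll_societal_spec`.
#' @return The parameter set with the specification attached.
#' @export
apply_societal <- function(params, spec) {
  stopifnot(inherits(params, "cll_parameter_set"), inherits(spec, "cll_societal_spec"))
  params$societal <- spec
  params
}
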