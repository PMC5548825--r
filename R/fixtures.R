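## Published per-cycle state costs and utility weights (GBP, 2013 price year).
## These are the in-model fixtures; every other scalar the model consumes is a
## named parameter (see generate_parameter_set()).

# Internal master table of per-cycle state costs. `key` is the canonical cost
# key bound to model states; `group` records which strategies the printed value
# applies to. Ibrutinib per-cycle costs are not listed here because they are
# decomposed into drug + care parameters (see generate_parameter_set); the
# printed totals (2704 Int, 2780 B) are reproduced by the parameter defaults.
.fixture_cache <- new.env(parent = emptyenv())

.state_cost_table <- function() {
  if (!is.null(.fixture_cache$costs)) return(.fixture_cache$costs)
  rows <- list(
    # key,            group,   cost,  printed state label
    c("fcr_l1_c1",    "ab",    4404,  "FCR treatment (first-line, first cycle)"),
    c("fcr_l1_c1",    "c",     4123,  "FCR treatment (first-line, first cycle)"),
    c("fcr_l1_c1",    "int",   3958,  "FCR treatment (first-line, first cycle)"),
    c("fcr_l2_c1",    "ab",    5373,  "FCR treatment (second-line, first cycle)"),
    c("fcr_l2_c1",    "c",     5092,  "FCR treatment (second-line, first cycle)"),
    c("fcr_l1_sub",   "abc",   4289,  "FCR treatment (subsequent cycles, first-line)"),
    c("fcr_l2_sub",   "abc",   5258,  "FCR treatment (subsequent cycles, second-line)"),
    c("fcr_l1_sub",   "int",   3805,  "FCR treatment (subsequent cycles)"),
    c("br_l1_c1",     "ab",    4535,  "BR treatment (first-line, first cycle)"),
    c("br_l1_c1",     "c",     4254,  "BR treatment (first-line, first cycle)"),
    c("br_l2_c1",     "ab",    5542,  "BR treatment (second-line, first cycle)"),
    c("br_l2_c1",     "c",     5261,  "BR treatment (second-line, first cycle)"),
    c("br_l2_c1",     "int",   4573,  "BR treatment (second-line, first cycle)"),
    c("br_l1_sub",    "abc",   4427,  "BR treatment (subsequent cycles, first-line)"),
    c("br_l2_sub",    "abc",   5434,  "BR treatment (subsequent cycles, second-line)"),
    c("br_l2_sub",    "int",   4427,  "BR treatment (subsequent cycles)"),
    c("ofa_l1_c1",    "ab",    12798, "Ofatumumab treatment (first-line, first cycle)"),
    c("ofa_l1_c1",    "int2",  12836, "Ofatumumab treatment (first-line, first cycle)"),
    c("ofa_l1_c2",    "ab",    15334, "Ofatumumab treatment (first-line, second cycle)"),
    c("ofa_l1_sub",   "ab",    4455,  "Ofatumumab treatment (first-line, subsequent cycles)"),
    c("ofa_ref_c1",   "ab",    13054, "Ofatumumab treatment (second-line or refractory, first cycle)"),
    c("ofa_ref_c1",   "c",     12773, "Ofatumumab treatment (second-line or refractory, first cycle)"),
    c("ofa_ref_c2",   "abc",   15590, "Ofatumumab treatment (second-line or refractory, second cycle)"),
    c("ofa_ref_sub",  "abc",   4711,  "Ofatumumab treatment (second-line or refractory, subsequent cycles)"),
    c("rem_fcr",      "all",   212,   "Remission following FCR treatment (all lines)"),
    c("rem_br",       "all",   130,   "Remission following BR treatment (all lines)"),
    c("rem_ofa",      "abci2", 49,    "Remission following ofatumumab treatment (all lines)"),
    c("bmt",          "abci2", 43724, "Undergoing BMT"),
    c("rem_bmt",      "abci2", 233,   "Remission following BMT"),
    c("bsc",          "all",   1650,  "BSC")
  )
  out <- data.frame(
    key   = vapply(rows, `[`, "", 1L),
    group = vapply(rows, `[`, "", 2L),
    cost  = as.numeric(vapply(rows, `[`, "", 3L)),
    state = vapply(rows, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  .fixture_cache$costs <- out
  out
}

# Which strategy names belong to each group tag.
.cost_group_members <- list(
  ab    = c("A", "B"),
  c     = "C",
  int   = c("Int1", "Int2"),
  int2  = "Int2",
  abc   = c("A", "B", "C"),
  abci2 = c("A", "B", "C", "Int2"),
  all   = c("A", "B", "C", "Int1", "Int2")
)

#' Published per-cycle health-state costs
#'
#' Cost of spending one 28-day cycle in each model health state, in GBP (2013),
#' by strategy group. First-cycle, second-cycle and subsequent-cycle entries
#' for chemotherapy lines are distinct keys; the BMT entry is the one-off cost
#' of the single-cycle transplant tunnel state.
#'
#' @return A data frame with columns `key` (canonical cost key), `group`
#'   (strategy group the value applies to), `cost` (GBP per cycle) and `state`
#'   (human-readable state label).
#' @export
published_state_costs <- function() .state_cost_table()

#' Look up the per-cycle cost of a state for a strategy
#'
#' @param key Canonical cost key (see [published_state_costs()]).
#' @param strategy One of "A", "B", "C", "Int1", "Int2".
#' @return Cost in GBP per 28-day cycle.
#' @details No ofatumumab second/subsequent-cycle first-line entry is published
#'   for Intervention 2; those states are bound to the A/B values (the printed
#'   first-cycle difference is £38, attributable to test-cost apportionment).
#' @export
state_cost <- function(key, strategy) {
  tab <- .state_cost_table()
  hit <- tab[tab$key == key &
               vapply(tab$group, function(g)
                 strategy %in% .cost_group_members[[g]], TRUE), , drop = FALSE]
  if (nrow(hit) == 0L && strategy == "Int2" && key %in% c("ofa_l1_c2", "ofa_l1_sub")) {
    hit <- tab[tab$key == key & tab$group == "ab", , drop = FALSE]
  }
  if (nrow(hit) != 1L)
    stop_named("no published state cost for key '%s' under strategy '%s'", key, strategy)
  hit$cost
}

#' Published utility weights
#'
#' Utility weights used to convert life-years to QALYs, including the grade-3/4
#' adverse-event disutility of -0.133.
#'
#' @return A data frame with columns `state` and `utility`.
#' @export
published_utility_weights <- function() {
  data.frame(
    state = c("first_line_treatment", "second_line_treatment",
              "refractory_treatment", "bmt", "remission",
              "grade34_ae_disutility", "bsc"),
    utility = c(0.803, 0.710, 0.650, 0.650, 0.910, -0.133, 0.680),
    stringsAsFactors = FALSE
  )
}

#' Look up a utility weight by state label
#' @param state One of the labels in [published_utility_weights()].
#' @return The utility weight.
#' @export
utility_weight <- function(state) {
  tab <- published_utility_weights()
  i <- match(state, tab$state)
  if (is.na(i)) stop_named("no published utility weight for state '%s'", state)
  tab$utility[i]
}
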