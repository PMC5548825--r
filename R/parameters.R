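## Parameter sets: every scalar the model consumes, with base value, range and
## distribution family, plus run settings (discounting, horizon, thresholds).

PARAM_ROLES <- c("transition-probability", "state-cost", "one-off-cost",
                 "utility", "rate", "proportion", "societal-cost")
PARAM_DISTS <- c("beta", "gamma", "fixed")
.bounded_roles <- c("transition-probability", "utility", "proportion")

.default_settings <- function() {
  list(
    discount_rate_annual = 0.035,
    cycle_length_days    = 28L,
    horizon_years        = 30,
    cohort_size          = 10000L,
    starting_age_years   = 65,
    cv_default           = 0.10,
    thresholds_gbp       = c(20000, 30000, 50000),
    responder_delta      = 0.20,
    utility_mode         = "pre-adjusted",   # or "complication-rate"
    half_cycle_costs     = TRUE,
    half_cycle_outcomes  = TRUE,
    ibr_waning_rate      = 0                 # per-cycle decay of ibrutinib response benefit
  )
}

#' Construct a parameter set
#'
#' @param table Data frame with columns `name`, `value`, `low`, `high`, `role`,
#'   `dist`, `variance_source`.
#' @param settings Named list of run settings; missing entries take defaults
#'   (3.5% annual discounting, 28-day cycles, 30-year horizon, cohort of
#'   10,000, starting age 65, CV default 0.10, thresholds 20/30/50 thousand
#'   GBP, responder effect 0.20).
#' @param validate Check invariants (default TRUE).
#' @return An object of class `cll_parameter_set`.
#' @export
parameter_set <- function(table, settings = list(), validate = TRUE) {
  stopifnot(is.data.frame(table))
  need <- c("name", "value", "low", "high", "role", "dist", "variance_source")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop_named("parameter table lacks columns: %s", paste(missing_cols, collapse = ", "))
  table <- table[need]
  table$name <- as.character(table$name)
  rownames(table) <- NULL
  st <- .default_settings()
  unknown <- setdiff(names(settings), names(st))
  if (length(unknown))
    stop_named("unknown settings: %s", paste(unknown, collapse = ", "))
  st[names(settings)] <- settings
  ps <- structure(list(settings = st, table = table), class = "cll_parameter_set")
  if (validate) validate_parameter_set(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks the type invariants: probabilities/proportions/utilities in [0, 1],
#' costs nonnegative, low <= value <= high, distribution family consistent with
#' role (beta only for probabilities/proportions/utilities, gamma only for
#' costs/rates), positive horizon and cycle length, nonnegative discount rate.
#' Errors name the offending parameter.
#'
#' @param ps A `cll_parameter_set`.
#' @return Invisibly, `ps`.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "cll_parameter_set"))
  st <- ps$settings
  if (st$discount_rate_annual < 0) stop_named("discount_rate_annual must be >= 0")
  if (st$horizon_years <= 0) stop_named("horizon_years must be > 0")
  if (st$cycle_length_days <= 0) stop_named("cycle_length_days must be > 0")
  if (!(st$utility_mode %in% c("pre-adjusted", "complication-rate")))
    stop_named("utility_mode must be 'pre-adjusted' or 'complication-rate'")
  if (st$responder_delta < 0 || st$responder_delta >= 1)
    stop_named("responder_delta must be in [0, 1)")
  tab <- ps$table
  if (anyDuplicated(tab$name))
    stop_named("duplicate parameter names: %s",
               paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  bad_role <- !tab$role %in% PARAM_ROLES
  if (any(bad_role))
    stop_named("parameter '%s' has unknown role '%s'",
               tab$name[bad_role][1], tab$role[bad_role][1])
  bad_dist <- !tab$dist %in% PARAM_DISTS
  if (any(bad_dist))
    stop_named("parameter '%s' has unknown distribution '%s'",
               tab$name[bad_dist][1], tab$dist[bad_dist][1])
  for (i in seq_len(nrow(tab))) {
    p <- tab[i, ]
    if (!is.finite(p$value) || !is.finite(p$low) || !is.finite(p$high))
      stop_named("parameter '%s' has non-finite value/range", p$name)
    if (p$role %in% .bounded_roles && (p$value < 0 || p$value > 1))
      stop_named("parameter '%s' (%s) must lie in [0, 1], got %g",
                 p$name, p$role, p$value)
    if (p$role %in% c("state-cost", "one-off-cost", "societal-cost", "rate") && p$value < 0)
      stop_named("parameter '%s' (%s) must be >= 0, got %g", p$name, p$role, p$value)
    if (p$low > p$value || p$value > p$high)
      stop_named("parameter '%s' violates low <= value <= high (%g, %g, %g)",
                 p$name, p$low, p$value, p$high)
    if (p$dist == "beta" && !(p$role %in% .bounded_roles))
      stop_named("parameter '%s': beta distribution is only valid for probabilities/utilities/proportions",
                 p$name)
    if (p$dist == "gamma" && !(p$role %in% c("state-cost", "one-off-cost",
                                             "societal-cost", "rate")))
      stop_named("parameter '%s': gamma distribution is only valid for costs/rates",
                 p$name)
  }
  invisible(ps)
}

#' Get a parameter value
#' @param ps A `cll_parameter_set`.
#' @param name Parameter name.
#' @return The base value.
#' @export
param_value <- function(ps, name) {
  i <- match(name, ps$table$name)
  if (is.na(i)) stop_named("unresolved parameter '%s'", name)
  ps$table$value[i]
}

.param_values <- function(ps, names) {
  i <- match(names, ps$table$name)
  if (anyNA(i))
    stop_named("unresolved parameter '%s'", names[which(is.na(i))[1]])
  ps$table$value[i]
}

#' Apply overrides to a parameter set
#'
#' Returns a new, re-validated set with the named overrides applied; the input
#' set is unchanged. Override names may refer to parameters or to scalar run
#' settings (e.g. `discount_rate_annual`, `horizon_years`,
#' `starting_age_years`, `responder_delta`).
#'
#' @param ps A `cll_parameter_set`.
#' @param overrides Named list or vector of replacement values.
#' @return A new `cll_parameter_set`.
#' @export
resolve <- function(ps, overrides = list()) {
  stopifnot(inherits(ps, "cll_parameter_set"))
  overrides <- as.list(overrides)
  if (length(overrides) == 0L) return(ps)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop_named("overrides must be named")
  tab <- ps$table
  st <- ps$settings
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    i <- match(nm, tab$name)
    if (!is.na(i)) {
      tab$value[i] <- v
      tab$low[i] <- min(tab$low[i], v)
      tab$high[i] <- max(tab$high[i], v)
    } else if (nm %in% names(st)) {
      st[[nm]] <- v
    } else {
      stop_named("unknown override name '%s'", nm)
    }
  }
  parameter_set(tab, st, validate = TRUE)
}

#' Write a parameter set to a YAML config file
#'
#' @param ps A `cll_parameter_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "cll_parameter_set"))
  tab <- ps$table
  params <- lapply(seq_len(nrow(tab)), function(i)
    list(value = tab$value[i], low = tab$low[i], high = tab$high[i],
         role = tab$role[i], dist = tab$dist[i],
         variance_source = tab$variance_source[i]))
  names(params) <- tab$name
  doc <- list(schema = "cllcea-parameters/1",
              settings = ps$settings,
              parameters = params)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load and validate a parameter set from a YAML config file
#'
#' The config dialect is YAML with three top-level keys: `schema`
#' (`"cllcea-parameters/1"`), `settings` and `parameters` (a map from
#' parameter name to `{value, low, high, role, dist, variance_source}`).
#' Unknown keys are rejected; all type invariants are checked and the set must
#' resolve every parameter referenced by any of the five strategies.
#'
#' @param path Path to a YAML config.
#' @param check_complete Also verify that every state of every strategy can
#'   bind its parameters (default TRUE).
#' @return A validated `cll_parameter_set`.
#' @export
load_parameter_set <- function(path, check_complete = TRUE) {
  if (!file.exists(path)) stop_named("config file not found: %s", path)
  doc <- yaml::read_yaml(path)
  unknown <- setdiff(names(doc), c("schema", "settings", "parameters"))
  if (length(unknown))
    stop_named("unknown top-level config keys: %s", paste(unknown, collapse = ", "))
  if (!identical(doc$schema, "cllcea-parameters/1"))
    stop_named("unsupported or missing schema (expected 'cllcea-parameters/1')")
  if (is.null(doc$parameters)) stop_named("config has no 'parameters' section")
  entry_fields <- c("value", "low", "high", "role", "dist", "variance_source")
  rows <- lapply(names(doc$parameters), function(nm) {
    e <- doc$parameters[[nm]]
    missing_f <- setdiff(c("value", "role"), names(e))
    if (length(missing_f))
      stop_named("parameter '%s' is missing required key(s): %s",
                 nm, paste(missing_f, collapse = ", "))
    extra <- setdiff(names(e), entry_fields)
    if (length(extra))
      stop_named("parameter '%s' has unknown key(s): %s", nm,
                 paste(extra, collapse = ", "))
    data.frame(name = nm, value = e$value,
               low = e$low %||% e$value, high = e$high %||% e$value,
               role = e$role, dist = e$dist %||% "fixed",
               variance_source = e$variance_source %||% "cv-default",
               stringsAsFactors = FALSE)
  })
  settings <- doc$settings %||% list()
  if (!is.null(settings$thresholds_gbp))
    settings$thresholds_gbp <- as.numeric(unlist(settings$thresholds_gbp))
  ps <- parameter_set(do.call(rbind, rows), settings, validate = TRUE)
  if (check_complete) check_parameter_completeness(ps)
  ps
}

#' Check that a parameter set covers all five strategies
#'
#' Attempts to bind every state of every strategy (costs, utilities,
#' transition probabilities, test accuracy); reports the unresolved parameter
#' names if any are missing.
#'
#' @param ps A `cll_parameter_set`.
#' @return Invisibly, `ps`.
#' @export
check_parameter_completeness <- function(ps) {
  missing <- character()
  for (nm in STRATEGY_NAMES) {
    res <- tryCatch({
      build_state_space(build_strategy(nm, ps), ps)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      m <- regmatches(res, regexec("unresolved parameter '([^']+)'", res))[[1]]
      missing <- c(missing, if (length(m) == 2L) m[2] else res)
    }
  }
  if (length(missing))
    stop_named("parameter set incomplete: %s", paste(unique(missing), collapse = ", "))
  invisible(ps)
}

#' @export
print.cll_parameter_set <- function(x, ...) {
  cat(sprintf("<cll_parameter_set: %d parameters>\n", nrow(x$table)))
  cat(sprintf("  discount %.1f%%/yr, %d-day cycles, %g-year horizon, start age %g\n",
              100 * x$settings$discount_rate_annual, x$settings$cycle_length_days,
              x$settings$horizon_years, x$settings$starting_age_years))
  invisible(x)
}
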