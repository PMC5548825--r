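## Shared internal helpers.

DAYS_PER_YEAR <- 365.25

#' Convert an annual hazard rate to a per-cycle probability
#'
#' Uses the exponential-hazard relation p = 1 - exp(-h * cycle_days / 365.25),
#' the single rate-to-probability convention used throughout the model.
#'
#' @param hazard Annual hazard rate (>= 0).
#' @param cycle_days Cycle length in days (default 28).
#' @return Per-cycle probability in [0, 1).
#' @export
rate_to_prob <- function(hazard, cycle_days = 28) {
  stopifnot(all(hazard >= 0), cycle_days > 0)
  1 - exp(-hazard * cycle_days / DAYS_PER_YEAR)
}

#' Cycle length in years
#' @param cycle_days Cycle length in days.
#' @return Fraction of a year spanned by one cycle.
#' @keywords internal
cycle_years <- function(cycle_days = 28) cycle_days / DAYS_PER_YEAR

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
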