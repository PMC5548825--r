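## The five test-treatment strategies: three current-practice comparators
## (A: genetic testing, FCR-based pathways; B: A with ibrutinib as refractory
## treatment; C: no testing) and two genomic-testing interventions
## (Int1: likely FCR non-responders get first-line ibrutinib then best
## supportive care; Int2: they get first-line ofatumumab then refractory
## ibrutinib). Genomic strategies re-test before every new treatment line.

#' @export
STRATEGY_NAMES <- c("A", "B", "C", "Int1", "Int2")

#' Test specification for a strategy
#'
#' Resolves the accuracy and cost of the pre-treatment test from a parameter
#' set. The genetic test (FISH + Sanger) flags 7% of patients with a 78%
#' positive predictive value; the genomic test (targeted NGS) flags 17% with
#' 82% PPV.
#'
#' @param name "genetic", "genomic" or "none".
#' @param params A `cll_parameter_set`.
#' @return A list with class `cll_test_spec`: `name`, `flagged_fraction`,
#'   `positive_predictive_value`, `residual_pfs36`, `cost` (one-off, GBP).
#' @export
test_spec <- function(name = c("genetic", "genomic", "none"), params) {
  name <- match.arg(name)
  if (name == "none")
    return(structure(list(name = "none", flagged_fraction = 0,
                          positive_predictive_value = 0,
                          residual_pfs36 = NA_real_, cost = 0),
                     class = "cll_test_spec"))
  out <- list(
    name = name,
    flagged_fraction = param_value(params, sprintf("flagged_fraction_%s", name)),
    positive_predictive_value = param_value(params, sprintf("ppv_%s", name)),
    residual_pfs36 = param_value(params, sprintf("residual_pfs36_%s", name)),
    cost = param_value(params, sprintf("cost_test_%s", name))
  )
  if (out$flagged_fraction < 0 || out$flagged_fraction > 1 ||
      out$positive_predictive_value < 0 || out$positive_predictive_value > 1)
    stop_named("test proportions must lie in [0, 1]")
  structure(out, class = "cll_test_spec")
}

#' Split the cohort by test result and true responder status
#'
#' Flagged mass equals the test's flagged fraction; flagged true positives are
#' flagged_fraction x PPV. The test-negative (residual) group is split into
#' true negatives and false negatives by solving for the mixing weight under
#' which the residual group's implied 36-month progression-free proportion
#' equals the test's residual PFS figure (0.69 for the genetic test, printed;
#' generated self-consistently for the genomic test), given the responder and
#' non-responder PFS curves implied by the parameter set.
#'
#' @param test A `cll_test_spec`.
#' @param params A `cll_parameter_set` (needed for the residual split).
#' @return Named numeric vector of entry proportions summing to 1:
#'   `flagged_tp`, `flagged_fp`, `unflagged_tn`, `unflagged_fn` (or `all` = 1
#'   when `test$name == "none"`).
#' @export
stratify_cohort <- function(test, params) {
  stopifnot(inherits(test, "cll_test_spec"))
  if (test$name == "none") return(c(all = 1))
  ff <- test$flagged_fraction
  ppv <- test$positive_predictive_value
  S_resp <- pfs36_fcr(params, "resp")
  S_mut <- pfs36_fcr(params, "mut")
  if (S_resp <= S_mut)
    stop_named("responder PFS must exceed non-responder PFS to derive the residual split")
  w <- (test$residual_pfs36 - S_mut) / (S_resp - S_mut)
  w <- min(1, max(0, w))
  out <- c(flagged_tp = ff * ppv,
           flagged_fp = ff * (1 - ppv),
           unflagged_tn = (1 - ff) * w,
           unflagged_fn = (1 - ff) * (1 - w))
  if (any(out < 0) || abs(sum(out) - 1) > 1e-12)
    stop_named("stratification proportions invalid (sum %g)", sum(out))
  out
}

#' Apply the responder-effect adjustment to a transition row
#'
#' Patients correctly identified as FCR responders by genomic testing receive
#' probabilities reflecting a `delta` (default 20%) improvement on standard
#' FCR treatment: mortality, non-response and progression probabilities are
#' each multiplied by (1 - delta) and the residual ("stay") mass absorbs the
#' difference, so the row still sums to 1.
#'
#' @param row Named numeric transition row summing to 1.
#' @param delta Improvement fraction in [0, 1).
#' @param events Names of the event entries to scale (default: all but `residual`).
#' @param residual Name of the entry that absorbs the freed mass (default "stay").
#' @return Adjusted row (same names, sums to 1).
#' @export
apply_responder_effect <- function(row, delta,
                                   events = setdiff(names(row), residual),
                                   residual = "stay") {
  if (delta < 0 || delta >= 1) stop_named("delta must be in [0, 1)")
  stopifnot(!is.null(names(row)), residual %in% names(row),
            all(events %in% names(row)))
  freed <- sum(row[events]) * delta
  row[events] <- row[events] * (1 - delta)
  row[residual] <- row[residual] + freed
  row
}

# One treatment line within a pathway chain.
.line <- function(trt, label, status, tunnel = 6L, bmt = FALSE, delta = FALSE) {
  list(trt = trt, label = label, status = status,
       tunnel = tunnel, bmt = bmt, delta = delta)
}

# The two chemotherapy orderings (FCR-first or BR-first) used by A/B/C.
.chemo_chains <- function(status, refractory_trt, p_blr, delta = FALSE,
                          acq = FALSE, ref_bmt = TRUE) {
  ref_line <- if (refractory_trt == "ibr")
    .line("ibr", "refractory", status, tunnel = Inf, bmt = FALSE)
  else
    .line("ofa", "refractory", status, bmt = ref_bmt)
  list(
    list(weight = 1 - p_blr, acq = acq,
         lines = list(.line("fcr", "first", status, delta = delta),
                      .line("br", "second", status, delta = delta),
                      ref_line)),
    list(weight = p_blr, acq = acq,
         lines = list(.line("br", "first", status),
                      .line("fcr", "second", status),
                      ref_line))
  )
}

#' Build a strategy
#'
#' Wires one of the five evaluated strategies: test specification, subcohort
#' entry proportions, and the treatment-line pathway of every subcohort.
#'
#' @param name One of "A", "B", "C", "Int1", "Int2".
#' @param params A `cll_parameter_set`.
#' @param test_override Optional `cll_test_spec` replacing the strategy's own
#'   test (used by the test-equalisation scenario).
#' @return An object of class `cll_strategy`.
#' @export
build_strategy <- function(name, params, test_override = NULL) {
  if (!name %in% STRATEGY_NAMES) stop_named("unknown strategy '%s'", name)
  delta <- params$settings$responder_delta
  p_blr <- param_value(params, "p_first_line_br")

  if (name %in% c("A", "B")) {
    test <- test_override %||% test_spec("genetic", params)
    ref_trt <- if (name == "B") "ibr" else "ofa"
    w <- stratify_cohort(test, params)
    flagged_chain <- function(status) list(list(
      weight = 1, acq = FALSE,
      lines = c(list(.line("ofa", "first", status, bmt = TRUE)),
                list(if (name == "B")
                  .line("ibr", "refractory", status, tunnel = Inf)
                else .line("ofa", "refractory", status, bmt = FALSE)))))
    subcohorts <- list(
      list(id = "flagged_tp", weight = w[["flagged_tp"]], chains = flagged_chain("mut")),
      list(id = "flagged_fp", weight = w[["flagged_fp"]], chains = flagged_chain("resp")),
      list(id = "unflagged_tn", weight = w[["unflagged_tn"]],
           chains = .chemo_chains("resp", ref_trt, p_blr, acq = TRUE)),
      list(id = "unflagged_fn", weight = w[["unflagged_fn"]],
           chains = .chemo_chains("mut", ref_trt, p_blr, acq = TRUE))
    )
    retest <- FALSE
  } else if (name == "C") {
    test <- test_override %||% test_spec("none", params)
    subcohorts <- list(
      list(id = "all", weight = 1,
           chains = .chemo_chains("unknown", "ofa", p_blr, acq = FALSE)))
    retest <- FALSE
  } else {
    test <- test_override %||% test_spec("genomic", params)
    w <- stratify_cohort(test, params)
    flagged_chain <- if (name == "Int1") {
      function(status) list(list(
        weight = 1, acq = FALSE,
        lines = list(.line("ibr", "first", status, tunnel = Inf))))
    } else {
      function(status) list(list(
        weight = 1, acq = FALSE,
        lines = list(.line("ofa", "first", status, bmt = TRUE),
                     .line("ibr", "refractory", status, tunnel = Inf))))
    }
    responder_chain <- function(status, with_delta) list(list(
      weight = 1, acq = FALSE,
      lines = list(.line("fcr", "first", status, delta = with_delta),
                   .line("br", "second", status, delta = with_delta),
                   .line("ibr", "refractory", status, tunnel = Inf))))
    subcohorts <- list(
      list(id = "flagged_tp", weight = w[["flagged_tp"]], chains = flagged_chain("mut")),
      list(id = "flagged_fp", weight = w[["flagged_fp"]], chains = flagged_chain("resp")),
      list(id = "unflagged_tn", weight = w[["unflagged_tn"]],
           chains = responder_chain("resp", TRUE)),
      list(id = "unflagged_fn", weight = w[["unflagged_fn"]],
           chains = responder_chain("mut", FALSE))
    )
    retest <- TRUE
  }
  structure(list(name = name, test = test, subcohorts = subcohorts,
                 responder_delta = delta, retest_per_line = retest),
            class = "cll_strategy")
}

#' Treatment/line pairs present in a strategy
#'
#' Structural audit helper: the set of (treatment, line) pairs that appear in
#' any subcohort's pathway.
#'
#' @param strategy A `cll_strategy`.
#' @return Data frame with columns `treatment` and `line`, unique rows.
#' @export
strategy_treatment_lines <- function(strategy) {
  rows <- list()
  for (sc in strategy$subcohorts)
    for (ch in sc$chains)
      for (ln in ch$lines)
        rows[[paste(ln$trt, ln$label)]] <- data.frame(
          treatment = ln$trt, line = ln$label, stringsAsFactors = FALSE)
  out <- do.call(rbind, unname(rows))
  out[order(out$treatment, out$line), , drop = FALSE]
}

#' @export
print.cll_strategy <- function(x, ...) {
  cat(sprintf("<cll_strategy %s: test = %s%s>\n", x$name, x$test$name,
              if (x$retest_per_line) ", re-tested per line" else ""))
  for (sc in x$subcohorts) {
    cat(sprintf("  %s (%.4f):\n", sc$id, sc$weight))
    for (ch in sc$chains) {
      path <- vapply(ch$lines, function(ln)
        sprintf("%s[%s,%s%s%s]", ln$trt, ln$label, ln$status,
                if (ln$bmt) ",+BMT" else "",
                if (isTRUE(ln$delta)) ",+effect" else ""), "")
      cat(sprintf("    %.2f: %s -> BSC%s\n", ch$weight,
                  paste(path, collapse = " -> "),
                  if (isTRUE(ch$acq)) "  (acquired-TP53 route to refractory)" else ""))
    }
  }
  invisible(x)
}
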