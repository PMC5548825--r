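## Tunnel-expanded Markov state spaces and cohort propagation.
##
## Convention: each non-absorbing state's row lists its event probabilities
## (non-response, progression, CLL death, ...) with the residual mass assigned
## to the state's persistence target (the next tunnel state, remission, or
## itself). Other-cause mortality is age-dependent and is added to each alive
## row additively at propagation time, taken out of the persistence entry, so
## rows always sum to 1 and a negative residual signals competing
## probabilities summing above 1.

# Resolve the cost parameter name for a canonical cost key under a strategy.
.cost_param_cache <- new.env(parent = emptyenv())

.cost_param_name <- function(key, strategy) {
  ck <- paste(key, strategy, sep = "|")
  hitc <- .cost_param_cache[[ck]]
  if (!is.null(hitc)) return(hitc)
  tab <- .state_cost_table()
  hit <- tab[tab$key == key &
               vapply(tab$group, function(g)
                 strategy %in% .cost_group_members[[g]], TRUE), , drop = FALSE]
  if (nrow(hit) == 0L && strategy == "Int2" && key %in% c("ofa_l1_c2", "ofa_l1_sub"))
    hit <- tab[tab$key == key & tab$group == "ab", , drop = FALSE]
  if (nrow(hit) != 1L)
    stop_named("no cost binding for key '%s' under strategy '%s'", key, strategy)
  out <- sprintf("cost_%s_%s", hit$key, hit$group)
  .cost_param_cache[[ck]] <- out
  out
}

.tunnel_cost_key <- function(trt, label, k) {
  stem <- if (label == "refractory") sprintf("%s_ref", trt)
  else sprintf("%s_l%d", trt, if (label == "first") 1L else 2L)
  part <- if (k == 1L) "c1" else if (k == 2L && trt == "ofa") "c2" else "sub"
  paste(stem, part, sep = "_")
}

.line_utility <- function(label, params) {
  param_value(params, switch(label,
                             first = "u_first_line",
                             second = "u_second_line",
                             refractory = "u_refractory"))
}

#' Build the tunnel-expanded state space for a strategy
#'
#' Expands every FCR/BR/ofatumumab treatment line into six 28-day tunnel
#' states (patients may leave any of them for the next line through
#' non-response, or die), gives ibrutinib a single unbounded treatment state,
#' attaches the one-cycle BMT tunnel plus BMT remission where a proportion of
#' patients completing an ofatumumab line is transplanted, and binds each
#' state's per-cycle cost and utility to the parameter set. One-off test costs
#' are charged on model entry and, for genomic strategies, on entry into every
#' later treatment line.
#'
#' @param strategy A `cll_strategy` (see [build_strategy()]).
#' @param params A `cll_parameter_set`.
#' @return An object of class `cll_state_space`.
#' @export
build_state_space <- function(strategy, params) {
  stopifnot(inherits(strategy, "cll_strategy"), inherits(params, "cll_parameter_set"))
  comp_mode <- identical(params$settings$utility_mode, "complication-rate")
  du <- if (comp_mode) param_value(params, "du_grade34_ae") else 0
  p_bmt <- param_value(params, "p_bmt")
  delta <- strategy$responder_delta

  states <- list()   # per-state metadata
  trans <- list()    # list of (from, to, prob)
  entry <- numeric()
  idx <- 0L
  new_state <- function(id, subcohort, role, treatment, line, tunnel_index,
                        cost, utility, entry_cost = 0, residual = NA_integer_) {
    idx <<- idx + 1L
    states[[idx]] <<- list(id = id, subcohort = subcohort, role = role,
                           treatment = treatment, line = line,
                           tunnel_index = tunnel_index, cost = cost,
                           utility = utility, entry_cost = entry_cost,
                           residual = residual)
    idx
  }
  link <- function(from, to, p) trans[[length(trans) + 1L]] <<- c(from, to, p)
  set_residual <- function(i, target) states[[i]]$residual <<- target

  pe <- list2env(as.list(stats::setNames(params$table$value, params$table$name)),
                 parent = emptyenv())
  pv <- function(name) {
    v <- get0(name, envir = pe, inherits = FALSE)
    if (is.null(v)) stop_named("unresolved parameter '%s'", name)
    v
  }
  comp_u <- function(base, trt) if (comp_mode)
    base - pv(sprintf("comp_rate_%s", trt)) * du else base

  test_cost <- strategy$test$cost
  retest <- strategy$retest_per_line

  for (sc in strategy$subcohorts) {
    death_cll <- new_state(sprintf("%s.death_cll", sc$id), sc$id, "death-cll",
                           "none", "none", NA, 0, 0)
    death_oth <- new_state(sprintf("%s.death_other", sc$id), sc$id, "death-other",
                           "none", "none", NA, 0, 0)
    set_residual(death_cll, death_cll); set_residual(death_oth, death_oth)
    for (ci in seq_along(sc$chains)) {
      ch <- sc$chains[[ci]]
      tag <- function(...) sprintf("%s.c%d.%s", sc$id, ci, sprintf(...))
      lines <- ch$lines
      nl <- length(lines)
      bsc <- new_state(tag("bsc"), sc$id, "bsc", "none", "none", NA,
                       pv(.cost_param_name("bsc", strategy$name)), pv("u_bsc"))
      set_residual(bsc, bsc)
      link(bsc, death_cll, pv("p_death_bsc"))

      entry_of <- integer(nl)      # entry state of each line (filled backwards)
      next_entry <- bsc
      ref_entry <- NA_integer_     # refractory entry for the acquired-TP53 route
      for (li in rev(seq_len(nl))) {
        ln <- lines[[li]]
        scale <- if (isTRUE(ln$delta)) 1 - delta else 1
        line_entry_cost <- if (retest && li > 1L) test_cost else 0
        if (ln$trt == "ibr") {
          p_nr <- pv("p_nonresp_ibr") * scale
          p_d <- pv("p_death_ibr") * scale
          st <- new_state(tag("ibr.%s", ln$label), sc$id, "treatment-tunnel",
                          "ibr", ln$label, NA,
                          pv("ibr_drug_cost_cycle") +
                            pv(if (strategy$name == "B") "ibr_care_cost_b"
                               else "ibr_care_cost_int"),
                          comp_u(.line_utility(ln$label, params), "ibr"),
                          entry_cost = line_entry_cost)
          set_residual(st, st)
          link(st, next_entry, p_nr)
          link(st, death_cll, p_d)
          entry_of[li] <- st
        } else {
          p_nr <- pv(sprintf("p_nonresp_%s_%s", ln$trt, ln$status)) * scale
          p_d <- pv(sprintf("p_death_%s_%s", ln$trt, ln$status)) * scale
          p_prog <- pv(sprintf("p_prog_rem_%s_%s", ln$trt, ln$status)) * scale
          ## remission after this line
          rem_key <- .cost_param_name(sprintf("rem_%s", ln$trt), strategy$name)
          rem <- new_state(tag("%s.%s.rem", ln$trt, ln$label), sc$id, "remission",
                           ln$trt, ln$label, NA, pv(rem_key), pv("u_remission"))
          set_residual(rem, rem)
          link(rem, next_entry, p_prog)
          if (isTRUE(ch$acq) && ln$label == "first" && !is.na(ref_entry))
            link(rem, ref_entry, pv("p_acq_tp53"))
          ## optional BMT consolidation on completing the line
          rem_target <- rem
          if (isTRUE(ln$bmt)) {
            bmt_rem <- new_state(tag("%s.%s.bmt_rem", ln$trt, ln$label), sc$id,
                                 "bmt-remission", ln$trt, ln$label, NA,
                                 pv(.cost_param_name("rem_bmt", strategy$name)),
                                 pv("u_remission"))
            set_residual(bmt_rem, bmt_rem)
            link(bmt_rem, next_entry, pv("p_prog_rem_bmt"))
            bmt_t <- new_state(tag("%s.%s.bmt", ln$trt, ln$label), sc$id,
                               "bmt-tunnel", ln$trt, ln$label, 1L,
                               pv(.cost_param_name("bmt", strategy$name)),
                               comp_u(pv("u_bmt"), "bmt"))
            set_residual(bmt_t, bmt_rem)
            link(bmt_t, death_cll, pv("p_death_bmt"))
          }
          ## the six tunnel states, built backwards
          nxt <- NULL
          for (k in rev(seq_len(ln$tunnel))) {
            st <- new_state(tag("%s.%s.t%d", ln$trt, ln$label, k), sc$id,
                            "treatment-tunnel", ln$trt, ln$label, k,
                            pv(.cost_param_name(.tunnel_cost_key(ln$trt, ln$label, k),
                                                strategy$name)),
                            comp_u(.line_utility(ln$label, params), ln$trt),
                            entry_cost = if (k == 1L) line_entry_cost else 0)
            link(st, next_entry, p_nr)
            link(st, death_cll, p_d)
            if (k == ln$tunnel) {
              if (isTRUE(ln$bmt)) {
                set_residual(st, rem_target)
                ## residual split: (1 - p_bmt) to remission, p_bmt to the BMT tunnel
                link(st, bmt_t, (1 - p_nr - p_d) * p_bmt)
              } else set_residual(st, rem)
            } else set_residual(st, nxt)
            nxt <- st
          }
          entry_of[li] <- nxt
        }
        if (ln$label == "refractory") ref_entry <- entry_of[li]
        next_entry <- entry_of[li]
      }
      e1 <- entry_of[1]
      states[[e1]]$entry_cost <- states[[e1]]$entry_cost + test_cost
      entry[length(entry) + 1L] <- sc$weight * ch$weight
      names(entry)[length(entry)] <- states[[e1]]$id
    }
  }

  n <- length(states)
  ids <- vapply(states, `[[`, "", "id")
  meta <- data.frame(
    id = ids,
    subcohort = vapply(states, `[[`, "", "subcohort"),
    role = vapply(states, `[[`, "", "role"),
    treatment = vapply(states, `[[`, "", "treatment"),
    line = vapply(states, `[[`, "", "line"),
    tunnel_index = vapply(states, function(s) as.integer(s$tunnel_index %||% NA), 1L),
    cost = vapply(states, `[[`, 0, "cost"),
    utility = vapply(states, `[[`, 0, "utility"),
    entry_cost = vapply(states, `[[`, 0, "entry_cost"),
    stringsAsFactors = FALSE
  )
  residual <- vapply(states, function(s) s$residual, 1L)
  Tm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (tr in trans) {
    if (tr[3] < 0)
      stop_named("negative transition probability from '%s'", ids[tr[1]])
    Tm[tr[1], tr[2]] <- Tm[tr[1], tr[2]] + tr[3]
  }
  alive <- !(meta$role %in% c("death-cll", "death-other"))
  for (j in seq_len(n)) {
    if (!alive[j]) { Tm[j, j] <- 1; next }
    res <- 1 - sum(Tm[j, ])
    if (res < -1e-12)
      stop_named("negative residual (competing probabilities sum > 1) in state '%s'",
                 ids[j])
    Tm[j, residual[j]] <- Tm[j, residual[j]] + max(0, res)
  }
  ## other-cause death sink per subcohort
  oth_idx <- vapply(seq_len(n), function(j) {
    w <- which(meta$subcohort == meta$subcohort[j] & meta$role == "death-other")
    if (length(w)) w[1] else NA_integer_
  }, 1L)

  entry_vec <- numeric(n); names(entry_vec) <- ids
  entry_vec[names(entry)] <- entry
  if (abs(sum(entry_vec) - 1) > 1e-9)
    stop_named("entry distribution sums to %.12f, expected 1", sum(entry_vec))

  ## ibrutinib rows, for the optional waning-benefit adjustment
  ibr_rows <- which(meta$treatment == "ibr" & meta$role == "treatment-tunnel")
  ibr_next <- vapply(ibr_rows, function(j) {
    tg <- setdiff(which(Tm[j, ] > 0), c(j, which(meta$role == "death-cll")))
    if (length(tg)) tg[1] else NA_integer_
  }, 1L)

  structure(list(strategy = strategy$name, states = meta, T = Tm,
                 entry = entry_vec, alive = alive, residual = residual,
                 death_other = oth_idx,
                 ibr_rows = ibr_rows, ibr_next = ibr_next,
                 ibr_p_nr = Tm[cbind(ibr_rows, ibr_next)]),
            class = "cll_state_space")
}

#' Assemble a state space by hand
#'
#' Low-level constructor used for small illustrative or oracle models: supply
#' the conditional transition matrix directly.
#'
#' @param T Square transition matrix (rows sum to 1; absorbing rows identity).
#' @param entry Entry distribution (sums to 1).
#' @param roles Character vector of state roles (defaults: last state
#'   "death-cll", rest "remission").
#' @param costs,utilities,entry_costs Per-state bindings (default 0/1/0).
#' @param residual Persistence target index per state (default: self).
#' @param subcohort Subcohort label (default "all").
#' @return A `cll_state_space`.
#' @export
manual_state_space <- function(T, entry, roles = NULL, costs = NULL,
                               utilities = NULL, entry_costs = NULL,
                               residual = NULL, subcohort = "all") {
  n <- nrow(T)
  stopifnot(ncol(T) == n, length(entry) == n)
  ids <- rownames(T) %||% paste0("s", seq_len(n))
  roles <- roles %||% c(rep("remission", n - 1L), "death-cll")
  meta <- data.frame(id = ids, subcohort = subcohort, role = roles,
                     treatment = "none", line = "none",
                     tunnel_index = NA_integer_,
                     cost = costs %||% rep(0, n),
                     utility = utilities %||% rep(1, n),
                     entry_cost = entry_costs %||% rep(0, n),
                     stringsAsFactors = FALSE)
  alive <- !(roles %in% c("death-cll", "death-other"))
  oth <- which(roles == "death-other")
  dimnames(T) <- list(ids, ids)
  entry <- as.numeric(entry); names(entry) <- ids
  structure(list(strategy = "manual", states = meta, T = T, entry = entry,
                 alive = alive, residual = residual %||% seq_len(n),
                 death_other = rep(if (length(oth)) oth[1] else NA_integer_, n),
                 ibr_rows = integer(), ibr_next = integer(), ibr_p_nr = numeric()),
            class = "cll_state_space")
}

#' Discount factor for a model cycle
#'
#' @param cycle Cycle index (0-based); vectorised.
#' @param annual_rate Annual discount rate (default 0.035).
#' @param cycle_length_days Days per cycle (default 28).
#' @return (1 + rate)^(-cycle * cycle_length_days / 365.25); 1 at cycle 0.
#' @export
discount_factor <- function(cycle, annual_rate = 0.035, cycle_length_days = 28) {
  stopifnot(all(cycle >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-cycle * cycle_length_days / DAYS_PER_YEAR)
}

#' Number of whole model cycles in the horizon
#' @param params A `cll_parameter_set`.
#' @return floor(horizon_years * 365.25 / cycle_length_days); 391 in the base case.
#' @export
n_model_cycles <- function(params) {
  as.integer(floor(params$settings$horizon_years * DAYS_PER_YEAR /
                     params$settings$cycle_length_days))
}

#' Full transition row of a state at a given cycle
#'
#' Combines the state's conditional event row with the age-dependent
#' other-cause death probability at (starting_age + cycle * 28/365.25):
#' other-cause death is added and the same mass is removed from the state's
#' persistence entry, so the row sums to 1. Death states return the identity
#' row.
#'
#' @param space A `cll_state_space`.
#' @param state State id (name) or index.
#' @param cycle 0-based cycle index.
#' @param params A `cll_parameter_set`.
#' @return Named probability vector over successor states (sums to 1).
#' @export
transition_row <- function(space, state, cycle, params) {
  j <- if (is.character(state)) match(state, space$states$id) else state
  if (is.na(j) || j < 1 || j > nrow(space$T))
    stop_named("unknown state '%s'", as.character(state))
  row <- space$T[j, ]
  if (!space$alive[j]) return(row)
  st <- params$settings
  age <- st$starting_age_years + cycle * cycle_years(st$cycle_length_days)
  p_oc <- background_mortality(age, params)
  if (length(space$ibr_rows) && st$ibr_waning_rate > 0) {
    k <- match(j, space$ibr_rows)
    if (!is.na(k)) {
      p_nr <- min(0.95, space$ibr_p_nr[k] * (1 + st$ibr_waning_rate)^cycle)
      extra <- p_nr - space$ibr_p_nr[k]
      row[space$ibr_next[k]] <- row[space$ibr_next[k]] + extra
      row[j] <- row[j] - extra
    }
  }
  rt <- space$residual[j]
  row[rt] <- row[rt] - p_oc
  oc <- space$death_other[j]
  if (is.na(oc)) {
    if (p_oc > 0)
      stop_named("state space has no other-cause death state but background mortality is positive")
  } else row[oc] <- row[oc] + p_oc
  if (row[rt] < -1e-12)
    stop_named("negative residual (competing probabilities sum > 1) in state '%s' at cycle %d",
               space$states$id[j], cycle)
  row
}

#' Propagate a cohort through the model
#'
#' Deterministic cohort propagation: occupancy at cycle 0 is the entry
#' distribution and each subsequent cycle applies [transition_row()] to every
#' state. The number of cycles is floor(horizon_years * 365.25 / 28) (391 for
#' the 30-year base case) unless `n_cycles` is given.
#'
#' @param space A `cll_state_space`.
#' @param params A `cll_parameter_set`.
#' @param n_cycles Optional override of the cycle count.
#' @return A `cll_cohort_trace`: occupancy and arrival matrices
#'   ((n_cycles + 1) x n_states), cycle length and starting age.
#' @export
run_cohort <- function(space, params, n_cycles = NULL) {
  st <- params$settings
  N <- n_cycles %||% n_model_cycles(params)
  stopifnot(N >= 1)
  n <- nrow(space$T)
  dt <- cycle_years(st$cycle_length_days)
  ages <- st$starting_age_years + (0:(N - 1)) * dt
  p_oc <- background_mortality(ages, params)
  alive_idx <- which(space$alive)
  if (any(p_oc > 0) && anyNA(space$death_other[alive_idx]))
    stop_named("state space has no other-cause death state but background mortality is positive")
  ## precheck: persistence entries must dominate the other-cause probability
  res_entry <- space$T[cbind(alive_idx, space$residual[alive_idx])]
  if (length(res_entry) && max(p_oc) > min(res_entry) + 1e-12) {
    j <- alive_idx[which.min(res_entry)]
    stop_named("negative residual (competing probabilities sum > 1) in state '%s' at cycle %d",
               space$states$id[j], which(p_oc > min(res_entry))[1] - 1L)
  }
  ## scatter matrices for the other-cause adjustment: move p_oc * v[j] from
  ## the persistence entry of each alive state to its subcohort's death-other
  ## sink; Rarr is the same restricted to genuine inflows (persistence into a
  ## *different* state). Stored transposed and sparse for the propagation loop.
  use_oc <- any(p_oc > 0)
  if (use_oc) {
    na <- length(alive_idx)
    rt_a <- space$residual[alive_idx]
    oc_a <- space$death_other[alive_idx]
    tRadj <- Matrix::sparseMatrix(
      i = c(rt_a, oc_a), j = rep(alive_idx, 2L),
      x = rep(c(-1, 1), each = na), dims = c(n, n))
    mv <- which(rt_a != alive_idx)
    tRarr <- Matrix::sparseMatrix(
      i = c(rt_a[mv], oc_a), j = c(alive_idx[mv], alive_idx),
      x = c(rep(-1, length(mv)), rep(1, na)), dims = c(n, n))
  }
  tT <- Matrix::t(methods::as(space$T, "CsparseMatrix"))
  waning <- st$ibr_waning_rate
  has_waning <- length(space$ibr_rows) > 0 && waning > 0

  occ <- matrix(0, N + 1L, n, dimnames = list(NULL, space$states$id))
  arr <- occ
  occ[1L, ] <- space$entry
  arr[1L, ] <- space$entry
  diagT <- diag(space$T)
  v <- space$entry
  for (c in seq_len(N)) {
    w <- as.numeric(tT %*% v)
    if (use_oc) {
      vn <- w + p_oc[c] * as.numeric(tRadj %*% v)
      inflow <- w - v * diagT + p_oc[c] * as.numeric(tRarr %*% v)
    } else {
      vn <- w
      inflow <- w - v * diagT
    }
    if (has_waning) {
      p_nr_c <- pmin(0.95, space$ibr_p_nr * (1 + waning)^(c - 1L))
      extra <- (p_nr_c - space$ibr_p_nr) * v[space$ibr_rows]
      for (k in seq_along(space$ibr_rows)) {
        vn[space$ibr_rows[k]] <- vn[space$ibr_rows[k]] - extra[k]
        vn[space$ibr_next[k]] <- vn[space$ibr_next[k]] + extra[k]
        inflow[space$ibr_next[k]] <- inflow[space$ibr_next[k]] + extra[k]
      }
    }
    if (min(vn) < -1e-9)
      stop_named("propagation produced occupancy mass below 0 at cycle %d", c)
    occ[c + 1L, ] <- vn
    arr[c + 1L, ] <- pmax(0, inflow)
    v <- vn
  }
  structure(list(occupancy = occ, arrivals = arr, space = space,
                 cycle_length_days = st$cycle_length_days,
                 starting_age_years = st$starting_age_years,
                 n_cycles = N),
            class = "cll_cohort_trace")
}

#' Half-cycle-corrected effective occupancy
#'
#' Trapezoid form: the effective occupancy attributed to cycle c is the mean
#' of the occupancies at its two bounding cycle boundaries. A constant trace
#' is unchanged and total mass is preserved per cycle. The correction is
#' applied exactly once, inside [evaluate()].
#'
#' @param trace A `cll_cohort_trace` (or an occupancy matrix).
#' @return Matrix of effective occupancies (n_cycles x n_states).
#' @export
half_cycle_correct <- function(trace) {
  occ <- if (inherits(trace, "cll_cohort_trace")) trace$occupancy else trace
  N <- nrow(occ) - 1L
  (occ[seq_len(N), , drop = FALSE] + occ[seq_len(N) + 1L, , drop = FALSE]) / 2
}

#' Export a cohort trace as CSV
#' @param trace A `cll_cohort_trace`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_trace <- function(trace, path) {
  df <- data.frame(cycle = 0:trace$n_cycles, trace$occupancy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
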