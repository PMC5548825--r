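test_that("cohort stratification reproduces the printed test-accuracy products", {
  ps <- default_parameter_set()
  w_gen <- stratify_cohort(test_spec("genetic", ps), ps)
  expect_equal(unname(w_gen[["flagged_tp"]]), 0.07 * 0.78)
  expect_equal(unname(w_gen[["flagged_fp"]] + w_gen[["flagged_tp"]]), 0.07)
  expect_equal(sum(w_gen), 1)

  w_nom <- stratify_cohort(test_spec("genomic", ps), ps)
  expect_equal(unname(w_nom[["flagged_tp"]]), 0.17 * 0.82)
  expect_equal(unname(w_nom[["flagged_fp"]] + w_nom[["flagged_tp"]]), 0.17)
  expect_equal(sum(w_nom), 1)

  expect_equal(stratify_cohort(test_spec("none", ps), ps), c(all = 1))

  # mass balance holds across generated sets
  for (seed in 1:4) {
    s <- generate_parameter_set(synthesis_spec(seed = seed, noise_cv = 0.1))
    expect_equal(sum(stratify_cohort(test_spec("genetic", s), s)), 1)
    expect_equal(sum(stratify_cohort(test_spec("genomic", s), s)), 1)
  }
})

test_that("the responder effect scales event probabilities and conserves mass", {
  row <- c(progression = 0.10, death = 0.02, stay = 0.88)
  expect_identical(apply_responder_effect(row, 0), row)

  adj <- apply_responder_effect(row, 0.2)
  expect_equal(unname(adj[["progression"]]), 0.08)
  expect_equal(unname(adj[["death"]]), 0.016)
  expect_equal(sum(adj), 1)

  expect_error(apply_responder_effect(row, 1), "delta")
  expect_error(apply_responder_effect(row, -0.1), "delta")
})

test_that("strategy wirings match their specification", {
  ps <- default_parameter_set()
  tl <- function(nm) {
    x <- strategy_treatment_lines(build_strategy(nm, ps))
    sort(paste(x$treatment, x$line))
  }
  expect_identical(tl("A"), sort(c("fcr first", "fcr second", "br first",
                                   "br second", "ofa first", "ofa refractory")))
  expect_identical(tl("B"), sort(c("fcr first", "fcr second", "br first",
                                   "br second", "ofa first", "ibr refractory")))
  expect_identical(tl("C"), sort(c("fcr first", "fcr second", "br first",
                                   "br second", "ofa refractory")))
  expect_identical(tl("Int1"), sort(c("ibr first", "fcr first", "br second",
                                      "ibr refractory")))
  expect_identical(tl("Int2"), sort(c("ofa first", "fcr first", "br second",
                                      "ibr refractory")))

  # B differs from A only in the refractory treatment
  expect_identical(setdiff(tl("A"), tl("B")), "ofa refractory")
  expect_identical(setdiff(tl("B"), tl("A")), "ibr refractory")

  # only B and the interventions contain ibrutinib
  for (nm in STRATEGY_NAMES) {
    has_ibr <- "ibr" %in% strategy_treatment_lines(build_strategy(nm, ps))$treatment
    expect_identical(has_ibr, nm %in% c("B", "Int1", "Int2"), label = nm)
  }
  expect_error(build_strategy("Z", ps), "unknown strategy")
})

test_that("Comparator C is untested and has no first-line-to-refractory route", {
  ps <- default_parameter_set()
  sC <- build_strategy("C", ps)
  expect_identical(sC$test$name, "none")
  expect_identical(names(stratify_cohort(sC$test, ps)), "all")
  acq_flags <- unlist(lapply(sC$subcohorts, function(sc)
    vapply(sc$chains, function(ch) isTRUE(ch$acq), TRUE)))
  expect_false(any(acq_flags))

  # A and B do have the acquired-TP53 route in the chemotherapy subcohorts
  sA <- build_strategy("A", ps)
  acq_A <- unlist(lapply(sA$subcohorts, function(sc)
    vapply(sc$chains, function(ch) isTRUE(ch$acq), TRUE)))
  expect_true(any(acq_A))

  # structurally: no C first-line state reaches a refractory-line state in one step
  spC <- build_state_space(sC, ps)
  st <- spC$states
  first_line <- which(st$line == "first" &
                        st$role %in% c("treatment-tunnel", "remission"))
  ref_states <- which(st$line == "refractory")
  for (j in first_line)
    expect_equal(sum(transition_row(spC, j, 0, ps)[ref_states]), 0)
  # ... while in A the first-line remission can reach refractory treatment
  spA <- build_state_space(sA, ps)
  stA <- spA$states
  rem1 <- which(stA$line == "first" & stA$role == "remission" &
                  stA$subcohort == "unflagged_tn")[1]
  refA <- which(stA$line == "refractory")
  expect_gt(sum(transition_row(spA, rem1, 0, ps)[refA]), 0)
})

test_that("genomic strategies re-test before each new treatment line", {
  ps <- default_parameter_set()
  test_cost <- param_value(ps, "cost_test_genomic")
  for (nm in c("Int1", "Int2")) {
    sp <- build_state_space(build_strategy(nm, ps), ps)
    st <- sp$states
    # every entry state of a line beyond the first carries the test cost
    responder_entries <- st[grepl("\\.t1$", st$id) | (st$treatment == "ibr" &
                                                        st$role == "treatment-tunnel"), ]
    later <- responder_entries[responder_entries$line != "first", ]
    expect_true(all(later$entry_cost == test_cost), label = nm)
  }
  # genetic strategies test once, on entry only
  spA <- build_state_space(build_strategy("A", ps), ps)
  stA <- spA$states
  later_A <- stA[stA$line %in% c("second", "refractory") &
                   (grepl("\\.t1$", stA$id)), ]
  expect_true(all(later_A$entry_cost == 0))
  entry_states <- stA[spA$entry > 0, ]
  expect_true(all(entry_states$entry_cost == param_value(ps, "cost_test_genetic")))
})

test_that("the responder effect is wired only into correctly identified responders", {
  ps <- default_parameter_set()
  for (nm in c("Int1", "Int2")) {
    s <- build_strategy(nm, ps)
    for (sc in s$subcohorts) {
      deltas <- unlist(lapply(sc$chains, function(ch)
        vapply(ch$lines, function(ln) isTRUE(ln$delta), TRUE)))
      if (sc$id == "unflagged_tn") expect_true(any(deltas), label = paste(nm, sc$id))
      else expect_false(any(deltas), label = paste(nm, sc$id))
    }
  }
  # genetic-testing strategies carry no responder adjustment at all
  for (nm in c("A", "B", "C")) {
    s <- build_strategy(nm, ps)
    deltas <- unlist(lapply(s$subcohorts, function(sc)
      lapply(sc$chains, function(ch) vapply(ch$lines, function(ln)
        isTRUE(ln$delta), TRUE))))
    expect_false(any(deltas), label = nm)
  }
})

test_that("increasing the responder effect never decreases intervention life-years", {
  ps <- default_parameter_set()
  ly <- vapply(c(0, 0.2, 0.4), function(d) {
    psd <- resolve(ps, list(responder_delta = d))
    evaluate_strategies(psd, "Int2")$ly_undisc
  }, 0)
  expect_true(all(diff(ly) > 0))
})
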