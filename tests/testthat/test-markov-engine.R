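test_that("tunnel expansion matches the design: six states per chemotherapy line", {
  ps <- default_parameter_set()
  for (nm in STRATEGY_NAMES) {
    sp <- build_state_space(build_strategy(nm, ps), ps)
    st <- sp$states
    chemo <- st[st$role == "treatment-tunnel" & st$treatment != "ibr", ]
    # group tunnel states by their line (id minus the .t<k> suffix)
    grp <- sub("\\.t[0-9]+$", "", chemo$id)
    for (g in unique(grp))
      expect_identical(sort(chemo$tunnel_index[grp == g]), 1:6)
    # ibrutinib has no tunnel bound; BMT tunnel is a single cycle
    expect_true(all(is.na(st$tunnel_index[st$treatment == "ibr"])))
    expect_true(all(st$tunnel_index[st$role == "bmt-tunnel"] == 1L))
    expect_false(any(grepl("\\.t7$", st$id)))
  }
})

test_that("sixth tunnel states feed remission/BMT/next line/death only", {
  ps <- default_parameter_set()
  sp <- build_state_space(build_strategy("A", ps), ps)
  st <- sp$states
  t6 <- which(st$role == "treatment-tunnel" & st$tunnel_index == 6L)
  for (j in t6) {
    row <- transition_row(sp, j, 0, ps)
    succ_roles <- st$role[row > 0]
    expect_true(all(succ_roles %in% c("remission", "bmt-tunnel",
                                      "treatment-tunnel", "bsc", "death-cll",
                                      "death-other")))
    succ_tunnels <- st$tunnel_index[row > 0 & st$role == "treatment-tunnel"]
    expect_true(all(is.na(succ_tunnels) | succ_tunnels == 1L))  # next-line entry
  }
})

test_that("death states are absorbing and their mass is nondecreasing", {
  ps <- default_parameter_set()
  sp <- build_state_space(build_strategy("Int2", ps), ps)
  dead <- which(sp$states$role %in% c("death-cll", "death-other"))
  for (j in dead) {
    row <- transition_row(sp, j, 5, ps)
    expect_equal(unname(row[j]), 1)
    expect_equal(sum(row), 1)
  }
  tr <- run_cohort(sp, ps, n_cycles = 200)
  for (j in dead)
    expect_true(all(diff(tr$occupancy[, j]) >= -1e-14))
})

test_that("transition rows combine competing probabilities by complement arithmetic", {
  # progression 0.05, CLL death 0.02, other-cause 0.001 -> stay 0.929
  T <- matrix(c(0.93, 0.05, 0.02, 0,
                0, 1, 0, 0,
                0, 0, 1, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE,
              dimnames = list(c("rem", "prog", "dcll", "doth"),
                              c("rem", "prog", "dcll", "doth")))
  sp <- manual_state_space(T, entry = c(1, 0, 0, 0),
                           roles = c("remission", "remission", "death-cll",
                                     "death-other"))
  ps <- tiny_params(gompertz_a = gompertz_a_for(0.001))
  row <- transition_row(sp, "rem", 0, ps)
  expect_equal(unname(row), c(0.929, 0.05, 0.02, 0.001), tolerance = 1e-12)
  expect_equal(sum(row), 1)
})

test_that("a 2-state toy reproduces the 0.9^c closed form exactly", {
  sp <- two_state_space(p = 0.1)
  tr <- run_cohort(sp, tiny_params(), n_cycles = 20)
  expect_equal(tr$occupancy[, "alive"], 0.9^(0:20), tolerance = 1e-14)
  expect_equal(rowSums(tr$occupancy), rep(1, 21), tolerance = 1e-14)
})

test_that("mass is conserved when no death is possible", {
  sp <- two_state_space(p = 0)
  tr <- run_cohort(sp, tiny_params(), n_cycles = 50)
  expect_equal(tr$occupancy[, "alive"], rep(1, 51))
})

test_that("the base case runs 391 cycles with conservation at 1e-10", {
  ps <- default_parameter_set()
  expect_identical(n_model_cycles(ps), 391L)
  sp <- build_state_space(build_strategy("A", ps), ps)
  tr <- run_cohort(sp, ps)
  expect_identical(nrow(tr$occupancy), 392L)
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
})

test_that("cohort propagation matches brute-force path enumeration", {
  # 4-state toy with age-varying other-cause mortality, 8 cycles
  T <- matrix(c(0, 0.95, 0.05, 0,
                0.2, 0.77, 0.03, 0,
                0, 0, 1, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE,
              dimnames = list(c("t1", "rem", "dcll", "doth"),
                              c("t1", "rem", "dcll", "doth")))
  sp <- manual_state_space(T, entry = c(1, 0, 0, 0),
                           roles = c("treatment-tunnel", "remission",
                                     "death-cll", "death-other"),
                           residual = c(2L, 2L, 3L, 4L))
  a <- 0.013 / exp(0.095 * 65)
  ps <- tiny_params(gompertz_a = a, gompertz_b = 0.095)

  # oracle: per-cycle matrices written out from the toy's definition
  Tfun <- function(cycle) {
    age <- 65 + cycle * 28 / 365.25
    p_oc <- 1 - exp(-a * exp(0.095 * age) * 28 / 365.25)
    M <- T
    M[1, 2] <- M[1, 2] - p_oc; M[1, 4] <- p_oc   # residual of t1 is remission
    M[2, 2] <- M[2, 2] - p_oc; M[2, 4] <- p_oc   # residual of rem is itself
    M
  }
  oracle <- brute_force_occupancy(Tfun, c(1, 0, 0, 0), 8)
  tr <- run_cohort(sp, ps, n_cycles = 8)
  expect_equal(unname(tr$occupancy), oracle, tolerance = 1e-8)

  # 3-state chain, 10 cycles, constant background mortality
  T2 <- matrix(c(0.8, 0.15, 0.05,
                 0, 0.9, 0.1,
                 0, 0, 1), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "dead"), c("a", "b", "dead")))
  sp2 <- manual_state_space(T2, entry = c(0.6, 0.4, 0),
                            roles = c("remission", "remission", "death-cll"))
  oracle2 <- brute_force_occupancy(function(cycle) T2, c(0.6, 0.4, 0), 10)
  tr2 <- run_cohort(sp2, tiny_params(), n_cycles = 10)
  expect_equal(unname(tr2$occupancy), oracle2, tolerance = 1e-8)
})

test_that("arrival tracking reproduces inflows implied by path enumeration", {
  sp <- two_state_space(p = 0.1)
  tr <- run_cohort(sp, tiny_params(), n_cycles = 10)
  # inflow into death at cycle c is 0.9^(c-1) * 0.1
  expect_equal(tr$arrivals[2:11, "dead"], 0.9^(0:9) * 0.1, tolerance = 1e-12)
  expect_equal(tr$arrivals[1, ], c(alive = 1, dead = 0))
})

test_that("discount factors follow (1 + r)^(-t)", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(0:50, 0), rep(1, 51))
  one_year <- 365.25 / 28
  expect_equal(discount_factor(one_year, 0.035), 1 / 1.035, tolerance = 1e-12)
  d <- discount_factor(0:391, 0.035)
  expect_true(all(diff(d) < 0))
})

test_that("half-cycle correction is the trapezoid of successive occupancies", {
  const <- matrix(0.5, 6, 2)
  expect_equal(half_cycle_correct(const), matrix(0.5, 5, 2))

  sp <- two_state_space(p = 0.2)
  tr <- run_cohort(sp, tiny_params(), n_cycles = 10)
  eff <- half_cycle_correct(tr)
  expect_equal(unname(eff[1, "alive"]), 0.9)   # mean of 1.0 and 0.8
  expect_equal(unname(rowSums(eff)), rep(1, 10))  # mass preserved per cycle

  # deliberately not idempotent: the engine applies it exactly once
  twice <- half_cycle_correct(eff)
  expect_false(isTRUE(all.equal(twice, eff[seq_len(nrow(twice)), ])))
})

test_that("competing probabilities summing above 1 are reported", {
  ps <- resolve(default_parameter_set(),
                list(p_nonresp_fcr_mut = 0.7, p_death_fcr_mut = 0.4))
  expect_error(build_state_space(build_strategy("A", ps), ps),
               "negative residual")
})

test_that("the ibrutinib waning option reduces life-years and is off by default", {
  ps <- default_parameter_set()
  expect_identical(ps$settings$ibr_waning_rate, 0)
  base <- evaluate_strategies(ps, "Int1")
  ps_w <- resolve(ps, list(ibr_waning_rate = 0.02))
  waned <- evaluate_strategies(ps_w, "Int1")
  expect_lt(waned$ly, base$ly)
  expect_lt(waned$qaly, base$qaly)
  # conservation still holds under the time-varying rows
  sp <- build_state_space(build_strategy("Int1", ps_w), ps_w)
  tr <- run_cohort(sp, ps_w)
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
})

test_that("trace export writes a cycle-by-state CSV", {
  sp <- two_state_space(0.1)
  tr <- run_cohort(sp, tiny_params(), n_cycles = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, tmp)
  df <- read.csv(tmp, check.names = FALSE)
  expect_identical(df$cycle, 0:5)
  expect_equal(df$alive, 0.9^(0:5))
})
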