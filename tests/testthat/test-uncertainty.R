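test_that("beta and gamma parameterisations recover their moments", {
  ab <- beta_params(0.5, sqrt(1 / 12))
  expect_equal(unname(ab), c(1, 1), tolerance = 1e-12)   # uniform limit

  ab2 <- beta_params(0.803, 0.0803)   # CV 0.10 on the first-line utility
  nu <- 0.803 * (1 - 0.803) / 0.0803^2 - 1
  expect_equal(unname(ab2), c(0.803 * nu, (1 - 0.803) * nu), tolerance = 1e-12)
  m <- ab2["alpha"] / sum(ab2)
  v <- prod(ab2) / (sum(ab2)^2 * (sum(ab2) + 1))
  expect_equal(unname(m), 0.803, tolerance = 1e-12)
  expect_equal(unname(sqrt(v)), 0.0803, tolerance = 1e-12)
  expect_error(beta_params(0.5, 0.6), "infeasible")
  expect_error(beta_params(1.2, 0.1), "mean")

  gp <- gamma_params(1650, 165)    # BSC cost at CV 0.10
  expect_equal(unname(gp), c(100, 16.5), tolerance = 1e-12)
  for (mean in c(0.01, 3, 44000))  # shape 100 at CV 0.10 regardless of mean
    expect_equal(unname(gamma_params(mean, 0.1 * mean)["shape"]), 100,
                 tolerance = 1e-12)
  expect_equal(unname(gp["shape"] * gp["scale"]), 1650, tolerance = 1e-12)
  expect_equal(unname(sqrt(gp["shape"]) * gp["scale"]), 165, tolerance = 1e-12)
  expect_error(gamma_params(-1, 1), "> 0")
})

test_that("PSA sampling is seeded, reproducible and honours fixed parameters", {
  ps <- default_parameter_set()
  p1 <- sample_psa(ps, n_sims = 25, seed = 4L, strategies = c("A", "C"))
  p2 <- sample_psa(ps, n_sims = 25, seed = 4L, strategies = c("A", "C"))
  expect_identical(p1$draws, p2$draws)
  p3 <- sample_psa(ps, n_sims = 25, seed = 5L, strategies = c("A", "C"))
  expect_false(identical(p1$draws$cost, p3$draws$cost))

  # all-fixed set: every draw equals the deterministic evaluation
  tab <- ps$table
  tab$dist <- "fixed"
  ps_fixed <- parameter_set(tab, ps$settings)
  pf <- sample_psa(ps_fixed, n_sims = 3, seed = 1L, strategies = "C")
  det <- evaluate_strategies(ps_fixed, "C")
  for (s in 1:3)
    expect_equal(pf$draws$cost[pf$draws$sim == s], det$cost)
})

test_that("PSA draw means approach the deterministic values as CV vanishes", {
  ps <- default_parameter_set()
  ps$settings$cv_default <- 0.001
  det <- evaluate_strategies(ps, "A")
  p <- sample_psa(ps, n_sims = 200, seed = 9L, strategies = "A")
  expect_equal(mean(p$draws$cost), det$cost, tolerance = 0.01)
  expect_equal(mean(p$draws$qaly), det$qaly, tolerance = 0.01)
})

test_that("probabilities sharing a transition row are renormalised when needed", {
  ps <- resolve(default_parameter_set(),
                list(p_nonresp_fcr_mut = 0.60, p_death_fcr_mut = 0.34))
  p <- sample_psa(ps, n_sims = 20, seed = 2L, strategies = "A")
  expect_gt(p$n_renormalised, 0)
  expect_true(all(is.finite(p$draws$cost)))
})

test_that("CEAC probabilities sum to one and respect threshold logic", {
  # three synthetic strategies over 40 draws
  set.seed(31)
  draws <- do.call(rbind, lapply(1:40, function(s)
    data.frame(sim = s, strategy = c("X", "Y", "Z"),
               cost = c(100, 200, 300) + rnorm(3, 0, 20),
               qaly = c(1.0, 1.1, 1.3) + rnorm(3, 0, 0.05),
               ly = 1)))
  cc <- ceac(draws, thresholds = seq(0, 5000, by = 500))
  probs <- as.matrix(cc[, -1])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)), tolerance = 1e-12)

  # at threshold 0 the cheapest strategy in each draw wins
  win0 <- tapply(seq_len(nrow(draws)), draws$sim, function(i)
    draws$strategy[i][which.min(draws$cost[i])])
  expect_equal(unname(probs[1, "X"]), mean(win0 == "X"))

  # single strategy: probability 1 everywhere
  solo <- draws[draws$strategy == "X", ]
  cc1 <- ceac(solo, thresholds = c(0, 30000))
  expect_equal(cc1$X, c(1, 1))

  # exact ties split evenly
  tie <- data.frame(sim = c(1, 1), strategy = c("P", "Q"),
                    cost = c(50, 50), qaly = c(1, 1), ly = c(1, 1))
  cct <- ceac(tie, thresholds = 1000)
  expect_equal(cct$P, 0.5)
  expect_equal(cct$Q, 0.5)
})

test_that("a two-strategy Gaussian toy matches the closed-form CEAC", {
  n <- 10000
  set.seed(77)
  e1 <- 1; c1 <- rnorm(n, 10000, 1000)
  e2 <- rnorm(n, 1.2, 0.05); c2 <- rnorm(n, 15000, 2000)
  draws <- rbind(
    data.frame(sim = 1:n, strategy = "S1", cost = c1, qaly = e1, ly = e1),
    data.frame(sim = 1:n, strategy = "S2", cost = c2, qaly = e2, ly = e2))
  lams <- c(10000, 25000, 40000)
  cc <- ceac(draws, thresholds = lams)
  for (k in seq_along(lams)) {
    lam <- lams[k]
    mu <- lam * 0.2 - 5000
    sdv <- sqrt(lam^2 * 0.05^2 + 2000^2 + 1000^2)
    p_true <- pnorm(mu / sdv)
    mc_se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(cc$S2[k] - p_true), 3 * mc_se)
  }
})

test_that("univariate sensitivity analysis spans low/high for each parameter", {
  ps <- default_parameter_set()
  pars <- c("u_remission", "cost_bsc_all", "p_death_bsc")
  sa <- univariate_sa(ps, strategies = c("A", "C", "Int2"), effect = "qaly",
                      param_names = pars,
                      setting_ranges = list(discount_rate_annual = c(0.0175, 0.0525)))
  expect_identical(nrow(sa), 2L * (length(pars) + 1L))
  expect_true(all(sa$optimal %in% c("A", "C", "Int2")))
  # a 0% variation keeps the optimum
  sa0 <- univariate_sa(resolve(ps, list()), strategies = c("A", "C"),
                       param_names = character(0),
                       setting_ranges = list(
                         discount_rate_annual = rep(ps$settings$discount_rate_annual, 2)))
  expect_false(any(sa0$changed))
})

test_that("raising a state cost raises that strategy's mean cost only", {
  ps <- default_parameter_set()
  lohi <- lapply(c(825, 2475), function(v)         # BSC cost +-50%
    evaluate_strategies(resolve(ps, list(cost_bsc_all = v)), c("A", "C")))
  expect_gt(lohi[[2]]$cost[1], lohi[[1]]$cost[1])
  expect_gt(lohi[[2]]$cost[2], lohi[[1]]$cost[2])
  expect_equal(lohi[[1]]$qaly, lohi[[2]]$qaly)     # outcomes untouched
})

test_that("threshold search matches the analytic crossover of a linear decision", {
  ps <- default_parameter_set()
  strategies <- c("A", "Int1")
  lam <- 30000
  ev <- function(price)
    evaluate_strategies(resolve(ps, list(ibr_drug_cost_cycle = price)), strategies)
  r1 <- ev(1000); r2 <- ev(5000); r3 <- ev(3000)
  # Int1's cost is affine in the ibrutinib price; A's is untouched
  k <- (r2$cost[2] - r1$cost[2]) / 4000
  expect_equal(r3$cost[2], r1$cost[2] + 2000 * k, tolerance = 1e-8)
  expect_equal(r1$cost[1], r2$cost[1])
  # analytic price at which Int1's ICER against A equals the threshold
  dE <- r1$qaly[2] - r1$qaly[1]
  crossover <- 1000 + (lam * dE - (r1$cost[2] - r1$cost[1])) / k
  found <- threshold_search("ibr_drug_cost_cycle", c(1000, 9000), ps, "Int1",
                            lambda = lam, effect = "qaly", tol = 0.5,
                            strategies = strategies)
  expect_identical(found$status, "ok")
  expect_lt(abs(found$value - crossover), 1)

  # bracket insensitivity while the decision stays monotone
  found2 <- threshold_search("ibr_drug_cost_cycle", c(500, 12000), ps, "Int1",
                             lambda = lam, effect = "qaly", tol = 0.5,
                             strategies = strategies)
  expect_lt(abs(found2$value - found$value), 1.5)

  # degenerate brackets are flagged rather than bisected
  all_in <- threshold_search("ibr_drug_cost_cycle", c(100, 200), ps, "Int1",
                             lambda = lam, effect = "qaly",
                             strategies = strategies)
  expect_identical(all_in$status, "target-optimal-throughout")
  never <- threshold_search("ibr_drug_cost_cycle", c(20000, 30000), ps, "Int1",
                            lambda = lam, effect = "qaly",
                            strategies = strategies)
  expect_identical(never$status, "never-optimal")
})

test_that("scenario machinery reproduces its configurations", {
  ps <- default_parameter_set()
  # multiplier 1 is the identity
  s1_id <- run_scenario(1, ps, strategies = c("A", "Int1"),
                        ibrutinib_multiplier = 1)
  base <- evaluate_strategies(ps, c("A", "Int1"))
  expect_equal(s1_id$base_case$results, base)
  # multiplier 0.25 prices the drug component at 575/cycle
  s1 <- run_scenario(1, ps, strategies = c("A", "Int1"))
  expect_equal(param_value(s1$params, "ibr_drug_cost_cycle"), 575)
  expect_lt(s1$base_case$results$cost[2], base$cost[2])

  s3 <- run_scenario(3, ps, strategies = c("A", "Int2"))
  expect_equal(s3$params$settings$responder_delta, 0.40)

  s4 <- run_scenario(4, ps, strategies = c("A", "C"), age = 85)
  expect_equal(s4$params$settings$starting_age_years, 85)

  s5 <- run_scenario(5, ps, strategies = c("A", "C"))
  expect_equal(s5$params$settings$horizon_years, 10)
  expect_lt(s5$base_case$results$ly[1], base$ly[1])

  # scenario 7: genomic strategies run with the genetic test's cost and accuracy
  s7 <- run_scenario(7, ps, strategies = c("A", "Int1"))
  ts <- test_spec("genetic", ps)
  s7_int1 <- build_strategy("Int1", s7$params, test_override = ts)
  expect_equal(s7_int1$test$flagged_fraction, 0.07)
  expect_equal(s7_int1$test$cost, param_value(ps, "cost_test_genetic"))
  expect_false(isTRUE(all.equal(s7$base_case$results$cost[2], base$cost[2])))
})
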