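base_tm <- function() transition_model(0.15, 0.07, 0.02, 0.038, 0.05)

test_that("the transition matrix has the published rows and structure", {
  m <- build_transition_matrix(base_tm())
  expect_equal(unname(m["low", ]), c(0.83, 0.15, 0, 0.02))
  expect_equal(unname(m["moderate", ]), c(0, 0.892, 0.07, 0.038))
  expect_equal(unname(m["high", ]), c(0, 0, 0.95, 0.05))
  expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  # structural zeros: no skipping, no backward moves, dead absorbing
  expect_equal(m["low", "high"], 0)
  expect_true(all(m[lower.tri(m)] == 0))
  expect_equal(rowSums(m), rep(1, 4), ignore_attr = TRUE)
})

test_that("zero probabilities give the identity; incompatible rows error", {
  expect_equal(unname(unclass(build_transition_matrix(
    transition_model(0, 0, 0, 0, 0)))), diag(4))
  expect_error(build_transition_matrix(
    transition_model(0.99, 0.07, 0.02, 0.038, 0.05)), "negative")
})

test_that("the cohort trace is the repeated matrix product", {
  m <- build_transition_matrix(base_tm())
  s1 <- model_settings(horizon_years = 0.25)
  tr1 <- run_cohort(state_distribution(1, 0, 0, 0), m, s1)
  expect_equal(unname(unlist(tr1[2, dependence_levels()])),
               c(0.83, 0.15, 0, 0.02))
  s2 <- model_settings(horizon_years = 0.5)
  tr2 <- run_cohort(state_distribution(1, 0, 0, 0), m, s2)
  expect_equal(tr2$low[3], 0.83^2)
  # dead is absorbing
  trd <- run_cohort(state_distribution(0, 0, 0, 1), m, model_settings())
  expect_true(all(trd$dead == 1))
  expect_true(all(trd$low == 0))
})

test_that("traces conserve mass and are monotone where required", {
  set.seed(11)
  for (i in 1:20) {
    probs <- stats::runif(5, 0, 0.3)
    tm <- transition_model(probs[1], probs[2], probs[3], probs[4], probs[5])
    e <- stats::runif(4)
    e <- e / sum(e)
    tr <- run_cohort(state_distribution(e[1], e[2], e[3], e[4]),
                     build_transition_matrix(tm), model_settings())
    occ <- as.matrix(tr[, dependence_levels()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    expect_true(all(diff(tr$dead) >= -1e-15))    # dead non-decreasing
    expect_true(all(diff(tr$low) <= 1e-15))      # low non-increasing
    expect_true(all(tr$new_deaths >= -1e-15))
    expect_equal(tr$new_deaths, c(0, diff(tr$dead)))
  }
})

test_that("discounting follows the selected method", {
  s <- model_settings()  # one_step, first year undiscounted
  expect_equal(discount_factor(0:3, 0.035, s), rep(1, 4))
  expect_equal(discount_factor(4, 0.035, s), 1 / 1.035)
  expect_equal(discount_factor(39, 0.035, s), 1 / 1.035)
  expect_equal(discount_factor(0:39, 0, s), rep(1, 40))

  sa <- model_settings(discount_method = "annual")
  expect_equal(discount_factor(3, 0.035, sa), 1)
  expect_equal(discount_factor(4, 0.035, sa), 1 / 1.035)
  expect_equal(discount_factor(8, 0.035, sa), 1.035^-2)

  sc <- model_settings(discount_method = "cycle",
                       first_year_undiscounted = FALSE)
  expect_equal(discount_factor(4, 0.035, sc), 1.035^-1)
  expect_equal(discount_factor(1, 0.035, sc), 1.035^-0.25)

  # turning the first-year flag off only changes year-zero cycles (annual)
  sa0 <- model_settings(discount_method = "annual",
                        first_year_undiscounted = FALSE)
  expect_equal(discount_factor(4:40, 0.035, sa0),
               discount_factor(4:40, 0.035, sa))
  expect_equal(discount_factor(0:3, 0.035, sa0), rep(1, 4))  # floor(t/4) = 0
})

test_that("cost accumulation matches hand-computed single-cycle cases", {
  p <- base_params()
  m <- build_transition_matrix(p$transitions)

  # everyone dead at entry: no care, no death-event, zero cost
  trd <- run_cohort(state_distribution(0, 0, 0, 1), m, p$settings)
  expect_equal(accumulate_costs(trd, p$costs, settings = p$settings), 0)

  # one cycle of high-dependence care, valued at the entry state only
  s1 <- model_settings(horizon_years = 0.25, discount_rate_costs = 0,
                       include_final_row = FALSE)
  tr1 <- run_cohort(state_distribution(0, 0, 1, 0), m, s1)
  expect_equal(accumulate_costs(tr1, p$costs, settings = s1), 8510)

  # with the terminal row, the deaths of the first cycle are charged
  s1b <- model_settings(horizon_years = 0.25, discount_rate_costs = 0)
  expect_equal(accumulate_costs(run_cohort(state_distribution(0, 0, 1, 0),
                                           m, s1b),
                                p$costs, settings = s1b),
               8510 + 0.95 * 8510 + 0.05 * 3519)
})

test_that("QALY accumulation matches hand-computed single-cycle cases", {
  p <- base_params()
  m <- build_transition_matrix(p$transitions)
  trd <- run_cohort(state_distribution(0, 0, 0, 1), m, p$settings)
  expect_equal(accumulate_qalys(trd, p$utilities, p$settings), 0)

  s1 <- model_settings(horizon_years = 0.25, discount_rate_qalys = 0,
                       include_final_row = FALSE)
  tr1 <- run_cohort(state_distribution(1, 0, 0, 0), m, s1)
  expect_equal(accumulate_qalys(tr1, p$utilities, s1), 0.788 * 0.25)
})

test_that("the intervention cost is charged undiscounted at entry", {
  p <- base_params()
  iv <- intervention_spec(effect = 0, per_person_cost = 570)
  ctrl <- run_model(p)
  with_iv <- run_model(p, iv)
  expect_equal(with_iv$discounted_cost - ctrl$discounted_cost, 570)
  # alive-only denominator scales by the alive share at entry
  p2 <- base_params(intervention_denominator = "alive")
  expect_equal(run_model(p2, iv)$discounted_cost -
                 run_model(p2)$discounted_cost, 570 * 0.94)
})

test_that("discounted totals never exceed undiscounted ones", {
  p <- base_params()
  r <- run_model(p, intervention_spec(effect = 0.025))
  expect_lte(r$discounted_cost, r$undiscounted_cost)
  expect_lte(r$discounted_qalys, r$undiscounted_qalys)
  expect_lte(r$discounted_qalys,
             p$settings$horizon_years * max(p$utilities$values))
})

test_that("trace audit rows sum to the accumulated totals", {
  p <- base_params()
  r <- run_model(p, intervention_spec(effect = 0.05))
  audit <- trace_audit(r, p)
  expect_equal(sum(audit$disc_cycle_cost) + 570, r$discounted_cost)
  expect_equal(sum(audit$disc_cycle_qalys), r$discounted_qalys)
})

test_that("state-independent decrements leave incremental costs unchanged
           and barely move incremental QALYs", {
  p <- base_params()
  iv <- intervention_spec(effect = 0.075)
  net <- function(params) {
    ctrl <- run_model(params)
    trt <- run_model(params, iv)
    c(cost = trt$discounted_cost - ctrl$discounted_cost,
      qalys = trt$discounted_qalys - ctrl$discounted_qalys,
      ly = sum(discount_factor(0:40, 0.035, params$settings) *
                 rowSums(trt$trace[, alive_levels()]) * 0.25) -
        sum(discount_factor(0:40, 0.035, params$settings) *
              rowSums(ctrl$trace[, alive_levels()]) * 0.25))
  }
  plain <- net(p)
  dec <- 0.05
  p$utilities <- utility_set(0.788, 0.750, 0.714,
                             decrement_schedule = data.frame(age = 0,
                                                             decrement = dec))
  shifted <- net(p)
  expect_equal(shifted[["cost"]], plain[["cost"]])
  expect_lt(abs(shifted[["qalys"]] - plain[["qalys"]]),
            dec * abs(plain[["ly"]]) + 1e-12)
})

test_that("the microsimulation oracle agrees with the cohort trace", {
  p <- base_params()
  ctrl <- run_model(p)
  ms <- run_microsim(p, n = 20000, seed = 99)
  expect_lt(abs(ms$mean_cost - ctrl$discounted_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$mean_qalys - ctrl$discounted_qalys), 3 * ms$se_qalys)
})

test_that("negative decrements from a schedule are rejected", {
  p <- base_params()
  p$utilities$decrement_schedule <- data.frame(age = 80, decrement = -0.1)
  m <- build_transition_matrix(p$transitions)
  tr <- run_cohort(p$entry, m, p$settings)
  expect_error(accumulate_qalys(tr, p$utilities, p$settings), "negative")
})
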