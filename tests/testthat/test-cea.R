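entry60 <- function() state_distribution(0.60, 0.24, 0.10, 0.06)

test_that("the entry-effect operator moves donor-state fractions down", {
  d <- entry60()
  expect_equal(apply_intervention_effect(d, 0), d)
  expect_equal(unclass(apply_intervention_effect(d, 0.025)),
               c(low = 0.606, moderate = 0.2365, high = 0.0975, dead = 0.06))
  expect_equal(unclass(apply_intervention_effect(d, 0.025,
                                                 subgroup_only = TRUE)),
               c(low = 0.606, moderate = 0.234, high = 0.10, dead = 0.06))
  # dead share never changes; mass is conserved
  out <- apply_intervention_effect(d, 0.4)
  expect_equal(out[["dead"]], 0.06)
  expect_equal(sum(out), 1)
})

test_that("the absolute effect reading moves sample shares and can run out", {
  d <- entry60()
  out <- apply_intervention_effect(d, 0.025, mode = "absolute")
  expect_equal(unclass(out),
               c(low = 0.625, moderate = 0.24, high = 0.075, dead = 0.06))
  expect_error(apply_intervention_effect(d, 0.125, mode = "absolute"),
               "exceeds")
})

test_that("comparison classifies dominance and degenerate cases", {
  p <- base_params()
  ctrl <- run_model(p)
  dom <- compare(run_model(p, intervention_spec(effect = 0.10)), ctrl)
  expect_equal(dom$verdict, "dominant")
  expect_true(is.na(dom$icer))
  expect_lt(dom$net_cost, 0)
  expect_gt(dom$net_qalys, 0)

  same <- compare(ctrl, ctrl)
  expect_equal(same$verdict, "zero_qaly_diff")
  expect_equal(same$net_cost, 0)

  # antisymmetry of net components
  trt <- run_model(p, intervention_spec(effect = 0.05))
  ab <- compare(trt, ctrl)
  ba <- compare(ctrl, trt)
  expect_equal(ab$net_cost, -ba$net_cost)
  expect_equal(ab$net_qalys, -ba$net_qalys)
})

test_that("threshold classification uses the 20k and 30k bands", {
  mk <- function(icer, verdict = "icer", nq = 0.01) {
    structure(list(net_cost = icer * nq, net_qalys = nq, icer = icer,
                   verdict = verdict), class = "cea_result")
  }
  expect_equal(classify_against_threshold(mk(8509)), "cost_effective")
  expect_equal(classify_against_threshold(mk(20000)), "cost_effective")
  expect_equal(classify_against_threshold(mk(22924)), "potentially")
  expect_equal(classify_against_threshold(mk(31332)), "not_cost_effective")
  expect_equal(classify_against_threshold(mk(NA, "dominant")),
               "cost_effective")
  expect_equal(classify_against_threshold(mk(NA, "dominated")),
               "not_cost_effective")
  expect_equal(classify_against_threshold(mk(NA, "zero_qaly_diff")),
               "undefined")
})

test_that("net costs and QALYs are linear in the effect", {
  p <- base_params()
  ctrl <- run_model(p)
  net <- function(e, sub = FALSE) {
    r <- compare(run_model(p, intervention_spec(effect = e,
                                                per_person_cost = 0,
                                                subgroup_only = sub)), ctrl)
    c(r$net_cost, r$net_qalys)
  }
  for (sub in c(FALSE, TRUE)) {
    n1 <- net(0.025, sub)
    for (e in c(0.05, 0.075, 0.125)) {
      expect_equal(net(e, sub), (e / 0.025) * n1, tolerance = 1e-9)
    }
  }
})

test_that("the ICER is monotone non-increasing in the effect", {
  p <- base_params()
  ctrl <- run_model(p)
  icers <- vapply(c(0.02, 0.04, 0.06, 0.08), function(e) {
    compare(run_model(p, intervention_spec(effect = e)), ctrl)$icer
  }, numeric(1))
  expect_true(all(diff(icers) < 0))
})

test_that("the full effect decomposes additively over donor states", {
  p <- base_params()
  e <- 0.08
  ctrl <- run_model(p)
  net_of <- function(entry) {
    p2 <- p
    p2$entry <- entry
    r <- run_model(p2)
    c(r$discounted_cost - ctrl$discounted_cost,
      r$discounted_qalys - ctrl$discounted_qalys)
  }
  full <- net_of(apply_intervention_effect(p$entry, e))
  sub <- net_of(apply_intervention_effect(p$entry, e, subgroup_only = TRUE))
  d <- p$entry
  high_only <- net_of(state_distribution(d[["low"]],
                                         d[["moderate"]] + e * d[["high"]],
                                         d[["high"]] - e * d[["high"]],
                                         d[["dead"]]))
  expect_equal(full, sub + high_only, tolerance = 1e-9)
})

test_that("threshold-effect search finds the published grid answer", {
  p <- base_params()
  res <- threshold_effect_search(p, 570,
                                 grid = c(0.025, 0.05, 0.075, 0.10))
  expect_equal(res$effect, 0.075)
  expect_true(res$reachable)

  # any positive effect qualifies when willingness-to-pay is unbounded
  res_inf <- threshold_effect_search(p, 570, wtp = 1e12,
                                     grid = c(0.025, 0.05, 0.075, 0.10))
  expect_equal(res_inf$effect, 0.025)
})

test_that("continuous bisection lands on the threshold ICER", {
  p <- base_params()
  res <- threshold_effect_search(p, 1000, tol = 1e-6)
  expect_true(res$reachable)
  ctrl <- run_model(p)
  at <- compare(run_model(p, intervention_spec(effect = res$effect,
                                               per_person_cost = 1000)), ctrl)
  expect_equal(at$icer, 20000, tolerance = 1e-3)
  # just below the solution it is not yet cost-effective
  below <- compare(run_model(p, intervention_spec(effect = res$effect - 1e-3,
                                                  per_person_cost = 1000)),
                   ctrl)
  expect_gt(below$icer, 20000)
})

test_that("an unreachable threshold is reported, not fabricated", {
  p <- base_params()
  res <- threshold_effect_search(p, 1e9)
  expect_false(res$reachable)
  expect_true(is.na(res$effect))
})

test_that("the scenario suite is deterministic and validates its grid", {
  p <- base_params()
  expect_error(run_scenario_suite(p, effects = numeric(0)), "empty")
  expect_error(run_scenario_suite(p, effects = -0.1), ">= 0")
  expect_warning(out <- run_scenario_suite(p, effects = 0.025,
                                           perspective = "societal"),
                 "informal")
  expect_equal(nrow(out), 0)

  s1 <- run_scenario_suite(p, effects = c(0.025, 0.05), horizons = c(10, 5))
  s2 <- run_scenario_suite(p, effects = c(0.025, 0.05), horizons = c(10, 5))
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * (2 + 1))
  # reference rows carry the no-intervention cohort
  ref10 <- s1[s1$effect == 0 & s1$horizon_years == 10, ]
  expect_equal(ref10$cost_per_person, run_model(p)$discounted_cost)
})

test_that("societal scenarios run once informal costs are supplied", {
  p <- base_params()
  p$costs <- cost_set(1738, 3239, 8510, 3519,
                      informal = c(low = 2137, moderate = 1800, high = 600))
  out <- run_scenario_suite(p, effects = c(0.025, 0.10),
                            perspective = "societal")
  expect_equal(nrow(out), 3)
  hs <- run_scenario_suite(p, effects = c(0.025, 0.10))
  # informal care costs raise totals and (with cheaper informal care at
  # higher dependence) make the intervention look less favourable
  expect_gt(out$cost_per_person[1], hs$cost_per_person[1])
})

test_that("convention calibration searches the full grid and picks the
           published-anchor minimiser", {
  cal <- calibrate_conventions(base_params())
  expect_equal(nrow(cal$grid), 24)
  expect_equal(cal$best$discount_method, "one_step")
  expect_true(cal$best$include_final_row)
  expect_false(cal$best$half_cycle_correction)
  expect_equal(cal$best$intervention_denominator, "cohort")
  expect_equal(cal$best$abs_error, min(cal$grid$abs_error))
  # the winning conventions are the package defaults
  s <- model_settings()
  expect_equal(cal$settings$discount_method, s$discount_method)
  expect_equal(cal$settings$include_final_row, s$include_final_row)
})
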