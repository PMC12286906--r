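#' Apply the intervention effect to the entry distribution
#'
#' The hypothetical intervention acts only at model entry, moving people
#' one dependence level down. Under the default relative interpretation,
#' a fraction `e` of the moderate-state occupancy moves to low and a
#' fraction `e` of the high-state occupancy moves to moderate, both
#' computed from the pre-intervention proportions (simultaneous
#' application, so the result is additive over the two donor states).
#' With `subgroup_only = TRUE` only the moderate-to-low move applies.
#' Under `mode = "absolute"`, `e` is instead a share of the whole sample
#' (percentage points) moved from each donor state, which errors when a
#' donor state holds less than `e`.
#'
#' @param entry A [state_distribution()].
#' @param e Sample-level effect in `[0, 1]`.
#' @param subgroup_only Only move moderate to low.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return The post-intervention [state_distribution()].
#' @export
#' @examples
#' d <- state_distribution(0.60, 0.24, 0.10, 0.06)
#' apply_intervention_effect(d, 0.025)
#' apply_intervention_effect(d, 0.025, subgroup_only = TRUE)
apply_intervention_effect <- function(entry, e, subgroup_only = FALSE,
                                      mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (!is.finite(e) || e < 0 || e > 1) {
    stop("effect must be in [0, 1]", call. = FALSE)
  }
  l <- entry[["low"]]; m <- entry[["moderate"]]
  h <- entry[["high"]]; d <- entry[["dead"]]
  if (mode == "relative") {
    move_ml <- e * m
    move_hm <- if (subgroup_only) 0 else e * h
  } else {
    move_ml <- e
    move_hm <- if (subgroup_only) 0 else e
    if (move_ml > m + 1e-12 || move_hm > h + 1e-12) {
      stop("absolute effect exceeds a donor state's occupancy",
           call. = FALSE)
    }
  }
  out <- state_distribution(l + move_ml, m - move_ml + move_hm,
                            h - move_hm, d)
  if (any(out < -1e-12) || abs(sum(out) - 1) > 1e-12) {
    stop("intervention effect produced an invalid distribution",
         call. = FALSE)
  }
  out
}

#' Compare an intervention run against a control run
#'
#' Incremental cost and QALYs are the differences between the two
#' cohorts; the ICER is incremental cost over incremental QALYs,
#' computed from unrounded values. A strategy with lower cost and more
#' QALYs dominates (no ICER is reported); higher cost and fewer QALYs is
#' dominated.
#'
#' @param intervention_run [run_model()] result for the intervention
#'   cohort (run with its [intervention_spec()]).
#' @param control_run [run_model()] result for the no-intervention
#'   cohort, under otherwise identical settings.
#' @return A list of class `"cea_result"`: `cost_per_person`,
#'   `qalys_per_person` (intervention cohort), `control_cost`,
#'   `control_qalys`, `net_cost`, `net_qalys`, `icer` (`NA` unless
#'   verdict is `"icer"`), and `verdict` in `"dominant"`, `"dominated"`,
#'   `"icer"`, `"zero_qaly_diff"`.
#' @export
compare <- function(intervention_run, control_run) {
  net_cost <- intervention_run$discounted_cost - control_run$discounted_cost
  net_qalys <- intervention_run$discounted_qalys - control_run$discounted_qalys
  if (net_qalys == 0) {
    verdict <- "zero_qaly_diff"
    icer <- NA_real_
  } else if (net_cost < 0 && net_qalys > 0) {
    verdict <- "dominant"
    icer <- NA_real_
  } else if (net_cost > 0 && net_qalys < 0) {
    verdict <- "dominated"
    icer <- NA_real_
  } else {
    verdict <- "icer"
    icer <- net_cost / net_qalys
  }
  structure(
    list(cost_per_person = intervention_run$discounted_cost,
         qalys_per_person = intervention_run$discounted_qalys,
         control_cost = control_run$discounted_cost,
         control_qalys = control_run$discounted_qalys,
         net_cost = net_cost, net_qalys = net_qalys,
         icer = icer, verdict = verdict),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental cost-effectiveness result\n")
  cat(sprintf("  cost per person: GBP %s (control %s)\n",
              format(round(x$cost_per_person), big.mark = ","),
              format(round(x$control_cost), big.mark = ",")))
  cat(sprintf("  QALYs per person: %.3f (control %.3f)\n",
              x$qalys_per_person, x$control_qalys))
  cat(sprintf("  net cost GBP %.0f, net QALYs %.4f\n",
              x$net_cost, x$net_qalys))
  if (x$verdict == "icer") {
    cat(sprintf("  ICER: GBP %s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else if (x$verdict == "dominant") {
    cat("  Intervention dominates\n")
  } else if (x$verdict == "dominated") {
    cat("  Intervention is dominated\n")
  } else {
    cat("  No QALY difference; ICER undefined\n")
  }
  invisible(x)
}

#' Classify a result against a willingness-to-pay threshold
#'
#' England's decision threshold is 20,000 GBP/QALY; ICERs between the
#' threshold and 30,000 GBP/QALY are classed as having potential for
#' cost-effectiveness, above that as unlikely to be cost-effective.
#'
#' @param result A [compare()] result.
#' @param wtp Willingness-to-pay threshold, GBP/QALY.
#' @param upper Upper bound of the "potentially cost-effective" band.
#' @return One of `"cost_effective"`, `"potentially"`,
#'   `"not_cost_effective"`, `"undefined"`.
#' @export
#' @examples
#' # dominant results are cost-effective by construction
classify_against_threshold <- function(result, wtp = 20000, upper = 30000) {
  switch(result$verdict,
    dominant = "cost_effective",
    dominated = "not_cost_effective",
    zero_qaly_diff = "undefined",
    icer = {
      if (result$net_qalys < 0) {
        # cost-saving but QALY-losing: cost-effective only if saving
        # exceeds wtp per QALY lost
        if (result$icer >= wtp) "cost_effective" else "not_cost_effective"
      } else if (result$icer <= wtp) {
        "cost_effective"
      } else if (result$icer <= upper) {
        "potentially"
      } else {
        "not_cost_effective"
      }
    }
  )
}

cea_at_effect <- function(params, e, intervention_cost, subgroup_only,
                          mode = "relative", perspective = "health_social_care",
                          control_run = NULL) {
  if (is.null(control_run)) control_run <- run_model(params,
                                                     perspective = perspective)
  spec <- intervention_spec(effect = e, per_person_cost = intervention_cost,
                            subgroup_only = subgroup_only, mode = mode)
  compare(run_model(params, spec, perspective = perspective), control_run)
}

#' Smallest effect at which the intervention is cost-effective
#'
#' Searches for the minimal sample-level effect `e*` whose result is
#' classified cost-effective at the given threshold. With a `grid`, the
#' smallest qualifying grid value is returned; otherwise a continuous
#' bisection refines `e*` to `tol`. The ICER is checked to be monotone
#' non-increasing in `e` over the searched range (it is, because net
#' cost and net QALYs are linear in `e` with a positive fixed
#' intervention cost).
#'
#' @param params A [model_parameters()] bundle.
#' @param intervention_cost Per-person intervention cost, GBP.
#' @param wtp Willingness-to-pay threshold, GBP/QALY.
#' @param grid Optional vector of effects to search (e.g.
#'   `c(0.025, 0.05, 0.075, 0.10)`); `NULL` for continuous bisection.
#' @param tol Absolute tolerance on `e` for the bisection.
#' @param subgroup_only Restrict the effect to the moderate-to-low move.
#' @param mode Effect interpretation, see [apply_intervention_effect()].
#' @return A list with `effect` (the minimal `e`, or `NA` if no `e` in
#'   `[0, 1]` qualifies), `icer` at that effect, and `reachable`.
#' @export
#' @examples
#' p <- base_case_parameters()
#' threshold_effect_search(p, 570, grid = c(0.025, 0.05, 0.075, 0.10))$effect
threshold_effect_search <- function(params, intervention_cost, wtp = 20000,
                                    grid = NULL, tol = 1e-4,
                                    subgroup_only = FALSE,
                                    mode = "relative") {
  control <- run_model(params)
  qualifies <- function(e) {
    r <- cea_at_effect(params, e, intervention_cost, subgroup_only, mode,
                       control_run = control)
    classify_against_threshold(r, wtp = wtp) == "cost_effective"
  }
  icer_at <- function(e) {
    r <- cea_at_effect(params, e, intervention_cost, subgroup_only, mode,
                       control_run = control)
    if (r$verdict == "icer") r$icer else -Inf
  }

  if (!is.null(grid)) {
    if (!length(grid)) stop("effect grid is empty", call. = FALSE)
    grid <- sort(grid)
    ic <- vapply(grid, icer_at, numeric(1))
    defined <- is.finite(ic) & ic > -Inf
    if (any(diff(ic[ic > -Inf]) > 1e-6 * pmax(1, abs(ic[ic > -Inf])[-1]))) {
      stop("ICER is not monotone non-increasing over the effect grid",
           call. = FALSE)
    }
    ok <- vapply(grid, qualifies, logical(1))
    if (!any(ok)) {
      return(list(effect = NA_real_, icer = NA_real_, reachable = FALSE))
    }
    e_star <- grid[which(ok)[1L]]
    r <- cea_at_effect(params, e_star, intervention_cost, subgroup_only,
                       mode, control_run = control)
    return(list(effect = e_star, icer = r$icer, reachable = TRUE))
  }

  if (!qualifies(1)) {
    return(list(effect = NA_real_, icer = NA_real_, reachable = FALSE))
  }
  lo <- 0; hi <- 1
  if (qualifies(0)) hi <- tol  # degenerate: free or dominant at e = 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (qualifies(mid)) hi <- mid else lo <- mid
  }
  r <- cea_at_effect(params, hi, intervention_cost, subgroup_only, mode,
                     control_run = control)
  list(effect = hi, icer = r$icer, reachable = TRUE)
}

#' Run the deterministic sensitivity-analysis scenario suite
#'
#' One row per combination of effect, horizon, and intervention cost
#' (plus the no-intervention reference rows), under the requested
#' perspective and effect operator. This is the machinery behind the
#' published base-case and sensitivity tables: effects 2.5-10% at a
#' 570 GBP intervention over 10- and 5-year horizons; the sub-group
#' (moderate-to-low only) scenario; and the intervention-cost grid.
#'
#' @param params A [model_parameters()] bundle.
#' @param effects Sample-level effects (fractions, >= 0); must be
#'   non-empty.
#' @param horizons Horizons in years.
#' @param intervention_costs Per-person intervention costs, GBP.
#' @param subgroup_only Restrict the effect to the moderate-to-low move.
#' @param perspective Costing perspective; societal scenarios are
#'   skipped with a warning when informal costs are absent.
#' @param mode Effect interpretation.
#' @return A `data.frame` with one row per scenario: the grid columns,
#'   per-person cost and QALYs, net cost, net QALYs, `icer`, `verdict`,
#'   and the threshold `classification`.
#' @export
#' @examples
#' p <- base_case_parameters()
#' suite <- run_scenario_suite(p, effects = c(0.025, 0.05, 0.075, 0.10))
#' suite[, c("effect", "net_cost", "net_qalys", "icer", "verdict")]
run_scenario_suite <- function(params,
                               effects,
                               horizons = params$settings$horizon_years,
                               intervention_costs = 570,
                               subgroup_only = FALSE,
                               perspective = c("health_social_care",
                                               "societal"),
                               mode = "relative") {
  perspective <- match.arg(perspective)
  if (!length(effects)) stop("effects grid is empty", call. = FALSE)
  if (any(effects < 0)) stop("effects must be >= 0", call. = FALSE)
  if (perspective == "societal" && is.null(params$costs$informal)) {
    warning("societal scenarios skipped: no informal-care costs configured",
            call. = FALSE)
    return(data.frame())
  }
  rows <- list()
  for (hz in horizons) {
    p_h <- params
    s <- p_h$settings
    s$horizon_years <- hz
    s$n_cycles <- hz / s$cycle_length_years
    p_h$settings <- s
    control <- run_model(p_h, perspective = perspective)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = 0, horizon_years = hz, intervention_cost = NA_real_,
      subgroup_only = subgroup_only, perspective = perspective,
      cost_per_person = control$discounted_cost,
      qalys_per_person = control$discounted_qalys,
      net_cost = NA_real_, net_qalys = NA_real_,
      icer = NA_real_, verdict = "reference",
      classification = NA_character_)
    for (ic in intervention_costs) {
      for (e in effects) {
        r <- cea_at_effect(p_h, e, ic, subgroup_only, mode, perspective,
                           control_run = control)
        rows[[length(rows) + 1L]] <- data.frame(
          effect = e, horizon_years = hz, intervention_cost = ic,
          subgroup_only = subgroup_only, perspective = perspective,
          cost_per_person = r$cost_per_person,
          qalys_per_person = r$qalys_per_person,
          net_cost = r$net_cost, net_qalys = r$net_qalys,
          icer = r$icer, verdict = r$verdict,
          classification = classify_against_threshold(r))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the under-specified accounting conventions
#'
#' The published analysis leaves several accounting conventions
#' unstated: whether a half-cycle correction is used, whether the
#' per-person intervention cost is spread over the whole entry cohort or
#' the alive entrants, how the beyond-first-year discount is compounded,
#' and whether the terminal trace row accrues. This searches the full
#' convention grid and returns the combination minimising the summed
#' absolute error against two published base-case anchors: the 10-year
#' no-intervention per-person cost and the net cost at the smallest
#' published effect.
#'
#' @param params A [model_parameters()] bundle (conventions in its
#'   settings are overridden during the search).
#' @param anchor_cost Published 10-year no-intervention per-person cost,
#'   GBP (default 104371, the published base case).
#' @param anchor_net_cost Published net cost at `anchor_effect`
#'   (default 415 GBP).
#' @param anchor_effect Effect at which `anchor_net_cost` was reported.
#' @param intervention_cost Per-person intervention cost at the anchor.
#' @return A list with `settings` (a [model_settings()] carrying the
#'   winning conventions), `grid` (a `data.frame` of every combination
#'   and its errors), and `best` (the winning row).
#' @export
#' @examples
#' cal <- calibrate_conventions(base_case_parameters())
#' cal$best[, c("discount_method", "include_final_row", "abs_error")]
calibrate_conventions <- function(params,
                                  anchor_cost = 104371,
                                  anchor_net_cost = 415,
                                  anchor_effect = 0.025,
                                  intervention_cost = 570) {
  grid <- expand.grid(
    discount_method = c("one_step", "annual", "cycle"),
    include_final_row = c(TRUE, FALSE),
    half_cycle_correction = c(FALSE, TRUE),
    intervention_denominator = c("cohort", "alive"),
    stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    s <- p$settings
    s$discount_method <- grid$discount_method[i]
    s$include_final_row <- grid$include_final_row[i]
    s$half_cycle_correction <- grid$half_cycle_correction[i]
    s$intervention_denominator <- grid$intervention_denominator[i]
    p$settings <- s
    control <- run_model(p)
    r <- cea_at_effect(p, anchor_effect, intervention_cost, FALSE,
                       control_run = control)
    data.frame(cost_no_intervention = control$discounted_cost,
               net_cost = r$net_cost,
               abs_error = abs(control$discounted_cost - anchor_cost) +
                 abs(r$net_cost - anchor_net_cost))
  })
  grid <- cbind(grid, do.call(rbind, res))
  best <- grid[which.min(grid$abs_error), , drop = FALSE]
  s <- params$settings
  s$discount_method <- best$discount_method
  s$include_final_row <- best$include_final_row
  s$half_cycle_correction <- best$half_cycle_correction
  s$intervention_denominator <- best$intervention_denominator
  list(settings = s, grid = grid, best = best)
}
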