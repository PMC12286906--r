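#' Dependence levels of the model
#'
#' The model has four health states: low, moderate, and high dependence
#' (defined by Bristol Activities of Daily Living Scale bands 0-14, 15-29
#' and 30+), plus an absorbing dead state.
#'
#' @return Character vector of the four state names, in model order.
#' @export
#' @examples
#' dependence_levels()
dependence_levels <- function() {
  c("low", "moderate", "high", "dead")
}

#' Alive dependence levels
#'
#' @return Character vector of the three alive state names.
#' @export
alive_levels <- function() {
  c("low", "moderate", "high")
}

new_named_states <- function(x, what, states = dependence_levels()) {
  x <- as.numeric(x)
  if (length(x) != length(states)) {
    stop(sprintf("%s must have %d values (%s)", what, length(states),
                 paste(states, collapse = ", ")), call. = FALSE)
  }
  names(x) <- states
  x
}

#' State occupancy distribution
#'
#' Proportion of the cohort in each of the four states at one point in
#' time. Proportions must be non-negative and sum to one (checked by
#' [validate_parameters()], so that deliberately invalid distributions can
#' be constructed for testing).
#'
#' @param low,moderate,high,dead Occupancy proportions, each in `[0, 1]`.
#' @return A named numeric vector of class `"state_distribution"`.
#' @export
#' @examples
#' state_distribution(0.60, 0.24, 0.10, 0.06)
state_distribution <- function(low, moderate, high, dead) {
  x <- new_named_states(c(low, moderate, high, dead), "state_distribution")
  structure(x, class = "state_distribution")
}

#' Per-cycle transition probabilities
#'
#' Progression is stepwise and irreversible: low can move to moderate,
#' moderate to high, and every alive state can die. There is no direct
#' low-to-high move and no backward move.
#'
#' @param p_low_to_mod Per-cycle probability of moving low -> moderate.
#' @param p_mod_to_high Per-cycle probability of moving moderate -> high.
#' @param p_death_low,p_death_mod,p_death_high Per-cycle probabilities of
#'   death from each alive state.
#' @return A list of class `"transition_model"`.
#' @export
#' @examples
#' transition_model(0.15, 0.07, 0.02, 0.038, 0.05)
transition_model <- function(p_low_to_mod, p_mod_to_high,
                             p_death_low, p_death_mod, p_death_high) {
  structure(
    list(p_low_to_mod = as.numeric(p_low_to_mod),
         p_mod_to_high = as.numeric(p_mod_to_high),
         p_death_low = as.numeric(p_death_low),
         p_death_mod = as.numeric(p_death_mod),
         p_death_high = as.numeric(p_death_high)),
    class = "transition_model"
  )
}

#' Per-cycle care costs and the death-event cost
#'
#' Care costs are GBP per 3-month cycle per person alive in the state
#' (cost-year 2019/20). The death-event cost is a one-off non-elective
#' hospital admission charged in the cycle the death occurs. Informal-care
#' costs (per cycle, per alive state) are an optional add-on used only
#' under the societal perspective; no default values are shipped.
#'
#' @param low,moderate,high Care cost per cycle for each alive state (GBP).
#' @param death_event One-off cost attached to each death (GBP).
#' @param informal Optional named numeric vector (`low`, `moderate`,
#'   `high`) of per-cycle informal-care costs, or `NULL`.
#' @return A list of class `"cost_set"`.
#' @export
#' @examples
#' cost_set(1738, 3239, 8510, death_event = 3519)
cost_set <- function(low, moderate, high, death_event, informal = NULL) {
  if (!is.null(informal)) {
    informal <- new_named_states(informal[alive_levels()], "informal costs",
                                 alive_levels())
  }
  structure(
    list(care = new_named_states(c(low, moderate, high), "care costs",
                                 alive_levels()),
         death_event = as.numeric(death_event),
         informal = informal),
    class = "cost_set"
  )
}

#' Health-state utilities and the age-decrement schedule
#'
#' Utility index values for the alive states (dead is fixed at 0). The
#' decrement schedule is an optional lookup of additive utility decrements
#' by age, applied as the cohort ages through the model; the default is a
#' zero decrement at every age.
#'
#' @param low,moderate,high Utility index per alive state (typically within
#'   the EQ-5D-5L England index range `[-0.594, 1]`).
#' @param dead Utility of the dead state; must be 0.
#' @param decrement_schedule Optional `data.frame` with columns `age`
#'   (years) and `decrement` (additive utility decrement, >= 0). The
#'   decrement applied at a given age is the entry with the largest
#'   `age` not exceeding it (zero below the smallest tabulated age).
#' @return A list of class `"utility_set"`.
#' @export
#' @examples
#' utility_set(0.788, 0.750, 0.714)
utility_set <- function(low, moderate, high, dead = 0,
                        decrement_schedule = NULL) {
  if (!is.null(decrement_schedule)) {
    decrement_schedule <- as.data.frame(decrement_schedule)
    if (!all(c("age", "decrement") %in% names(decrement_schedule))) {
      stop("decrement_schedule needs columns 'age' and 'decrement'",
           call. = FALSE)
    }
    decrement_schedule <-
      decrement_schedule[order(decrement_schedule$age), c("age", "decrement")]
  }
  structure(
    list(values = new_named_states(c(low, moderate, high), "utilities",
                                   alive_levels()),
         dead = as.numeric(dead),
         decrement_schedule = decrement_schedule),
    class = "utility_set"
  )
}

#' Look up the age decrement for a utility set
#'
#' @param utilities A [utility_set()].
#' @param age Age(s) in years.
#' @return Numeric decrement(s), zero when no schedule is set.
#' @export
decrement_at_age <- function(utilities, age) {
  sched <- utilities$decrement_schedule
  if (is.null(sched) || nrow(sched) == 0L) {
    return(rep(0, length(age)))
  }
  idx <- findInterval(age, sched$age)
  out <- rep(0, length(age))
  out[idx > 0] <- sched$decrement[idx[idx > 0]]
  out
}

#' Model run settings and accounting conventions
#'
#' Structural settings (horizon, cycle length, discount rates, entry age)
#' together with the accounting conventions that the published tables
#' under-determine. The convention defaults are those selected by
#' [calibrate_conventions()] against the published base-case anchors; see
#' the package vignette for the calibration.
#'
#' @param horizon_years Model time horizon in years.
#' @param cycle_length_years Cycle length in years (3 months = 0.25).
#' @param discount_rate_costs,discount_rate_qalys Annual discount rates.
#' @param entry_age Cohort age at model entry, years.
#' @param cohort_size Reporting cohort size; all accounting is per person,
#'   this is used only for display and the microsimulation oracle default.
#' @param first_year_undiscounted If `TRUE` (default), amounts accrued in
#'   the first model year are not discounted.
#' @param discount_method One of `"one_step"` (a single division by
#'   `1 + rate` for everything beyond the first year; the calibrated
#'   default), `"annual"` (compound annual step: `(1 + rate)^-y` with `y`
#'   the completed-year index), or `"cycle"` (continuous per-cycle
#'   compounding).
#' @param include_final_row If `TRUE` (calibrated default), costs and
#'   QALYs accrue at every trace row `t = 0..n_cycles` (entry plus each
#'   end-of-transition occupancy); if `FALSE`, at `t = 0..n_cycles - 1`
#'   (start-of-cycle accrual).
#' @param half_cycle_correction If `TRUE`, the first and last accrual
#'   points carry half weight. Off in the calibrated base case.
#' @param intervention_denominator `"cohort"` (calibrated default: the
#'   per-person intervention cost is charged across the whole entry
#'   cohort, including those entering dead) or `"alive"`.
#' @return A list of class `"model_settings"`; `n_cycles` is derived as
#'   `horizon_years / cycle_length_years`.
#' @export
#' @examples
#' model_settings()                     # base case: 10 years, 40 cycles
#' model_settings(horizon_years = 5)    # 20 cycles
model_settings <- function(horizon_years = 10,
                           cycle_length_years = 0.25,
                           discount_rate_costs = 0.035,
                           discount_rate_qalys = 0.035,
                           entry_age = 80,
                           cohort_size = 1000,
                           first_year_undiscounted = TRUE,
                           discount_method = c("one_step", "annual", "cycle"),
                           include_final_row = TRUE,
                           half_cycle_correction = FALSE,
                           intervention_denominator = c("cohort", "alive")) {
  discount_method <- match.arg(discount_method)
  intervention_denominator <- match.arg(intervention_denominator)
  structure(
    list(horizon_years = as.numeric(horizon_years),
         cycle_length_years = as.numeric(cycle_length_years),
         n_cycles = as.numeric(horizon_years) / as.numeric(cycle_length_years),
         discount_rate_costs = as.numeric(discount_rate_costs),
         discount_rate_qalys = as.numeric(discount_rate_qalys),
         entry_age = as.numeric(entry_age),
         cohort_size = as.numeric(cohort_size),
         first_year_undiscounted = isTRUE(first_year_undiscounted),
         discount_method = discount_method,
         include_final_row = isTRUE(include_final_row),
         half_cycle_correction = isTRUE(half_cycle_correction),
         intervention_denominator = intervention_denominator),
    class = "model_settings"
  )
}

#' Hypothetical independence-preserving intervention
#'
#' The intervention acts once, at model entry, by moving a fraction `effect`
#' of the moderate-dependence occupancy down to low dependence and (unless
#' `subgroup_only`) the same fraction of the high-dependence occupancy down
#' to moderate. Both moves are taken from the pre-intervention proportions.
#' Transition probabilities after entry are unchanged.
#'
#' @param effect Sample-level effect `e` in `[0, 1]`: the fraction of each
#'   donor state's occupancy moved one level down (relative
#'   interpretation; see [apply_intervention_effect()] for the
#'   alternative absolute reading).
#' @param per_person_cost Intervention cost per person, GBP.
#' @param subgroup_only If `TRUE`, only the moderate-to-low move applies.
#' @param mode `"relative"` (default) or `"absolute"` effect
#'   interpretation, passed to [apply_intervention_effect()].
#' @return A list of class `"intervention_spec"`.
#' @export
#' @examples
#' intervention_spec(effect = 0.025)
intervention_spec <- function(effect, per_person_cost = 570,
                              subgroup_only = FALSE,
                              mode = c("relative", "absolute")) {
  structure(
    list(effect = as.numeric(effect),
         per_person_cost = as.numeric(per_person_cost),
         subgroup_only = isTRUE(subgroup_only),
         mode = match.arg(mode)),
    class = "intervention_spec"
  )
}

#' Bundle all model inputs
#'
#' @param entry A [state_distribution()]: cohort occupancy at model entry.
#' @param transitions A [transition_model()].
#' @param costs A [cost_set()].
#' @param utilities A [utility_set()].
#' @param settings A [model_settings()].
#' @return A list of class `"model_parameters"`.
#' @export
model_parameters <- function(entry, transitions, costs, utilities,
                             settings = model_settings()) {
  structure(
    list(entry = entry, transitions = transitions, costs = costs,
         utilities = utilities, settings = settings),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Dependence-state Markov model parameters\n")
  cat(sprintf("  entry: %s\n",
              paste(sprintf("%s %.3f", names(x$entry), x$entry),
                    collapse = ", ")))
  cat(sprintf("  progression: low->mod %.3f, mod->high %.3f per cycle\n",
              x$transitions$p_low_to_mod, x$transitions$p_mod_to_high))
  cat(sprintf("  death per cycle: %.3f / %.3f / %.3f\n",
              x$transitions$p_death_low, x$transitions$p_death_mod,
              x$transitions$p_death_high))
  cat(sprintf("  care cost per cycle (GBP): %s; death event %.0f\n",
              paste(sprintf("%.0f", x$costs$care), collapse = " / "),
              x$costs$death_event))
  cat(sprintf("  utilities: %s\n",
              paste(sprintf("%.3f", x$utilities$values), collapse = " / ")))
  cat(sprintf("  horizon %g y, %g cycles of %g y, discount %g%%/%g%% (%s)\n",
              x$settings$horizon_years, x$settings$n_cycles,
              x$settings$cycle_length_years,
              100 * x$settings$discount_rate_costs,
              100 * x$settings$discount_rate_qalys,
              x$settings$discount_method))
  invisible(x)
}

prob_ok <- function(p) is.finite(p) & p >= 0 & p <= 1

#' Validate a model-parameter bundle
#'
#' Checks every type invariant and reports all violations at once, naming
#' the offending fields. Returns the bundle unchanged (invisibly) when
#' everything holds.
#'
#' @param params A [model_parameters()] bundle.
#' @param perspective Costing perspective the bundle will be used under;
#'   `"societal"` additionally requires informal-care costs.
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
#' @examples
#' validate_parameters(base_case_parameters())
validate_parameters <- function(params,
                                perspective = c("health_social_care",
                                                "societal")) {
  perspective <- match.arg(perspective)
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  e <- params$entry
  if (!inherits(e, "state_distribution") || length(e) != 4L) {
    note("entry: not a four-state state_distribution")
  } else {
    if (any(!is.finite(e)) || any(e < 0)) {
      note("entry: proportions must be finite and >= 0")
    }
    if (abs(sum(e) - 1) > 1e-12) {
      note(sprintf("entry: proportions sum to %.12g, sum != 1", sum(e)))
    }
  }

  tm <- params$transitions
  for (f in c("p_low_to_mod", "p_mod_to_high",
              "p_death_low", "p_death_mod", "p_death_high")) {
    if (!prob_ok(tm[[f]])) {
      note(sprintf("transitions$%s: probability outside [0, 1]", f))
    }
  }
  if (isTRUE(tm$p_low_to_mod + tm$p_death_low > 1)) {
    note("transitions: low row exceeds 1 (p_low_to_mod + p_death_low > 1)")
  }
  if (isTRUE(tm$p_mod_to_high + tm$p_death_mod > 1)) {
    note("transitions: moderate row exceeds 1 (p_mod_to_high + p_death_mod > 1)")
  }

  co <- params$costs
  if (any(!is.finite(co$care)) || any(co$care < 0)) {
    note("costs$care: care costs must be finite and >= 0")
  }
  if (!is.finite(co$death_event) || co$death_event < 0) {
    note("costs$death_event: must be finite and >= 0")
  }
  if (!is.null(co$informal) && (any(!is.finite(co$informal)) ||
                                any(co$informal < 0))) {
    note("costs$informal: informal costs must be finite and >= 0")
  }
  if (perspective == "societal" && is.null(co$informal)) {
    note("costs$informal: required under the societal perspective")
  }

  u <- params$utilities
  if (u$dead != 0) {
    note("utilities$dead: utility of the dead state must be exactly 0")
  }
  if (any(!is.finite(u$values))) {
    note("utilities: alive-state values must be finite")
  }
  if (!is.null(u$decrement_schedule) &&
      any(u$decrement_schedule$decrement < 0)) {
    note("utilities$decrement_schedule: decrements must be >= 0")
  }

  s <- params$settings
  n <- s$horizon_years / s$cycle_length_years
  if (!is.finite(n) || n <= 0 || abs(n - round(n)) > 1e-9) {
    note(sprintf(
      "settings: horizon/cycle length gives non-integer cycle count (%.6g)", n))
  }
  if (s$discount_rate_costs < 0 || s$discount_rate_qalys < 0) {
    note("settings: discount rates must be >= 0")
  }

  if (length(bad)) {
    stop("invalid model parameters:\n",
         paste0("  - ", bad, collapse = "\n"), call. = FALSE)
  }
  invisible(params)
}

#' Validate an intervention specification
#'
#' @param spec An [intervention_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_intervention <- function(spec) {
  bad <- character(0)
  if (!prob_ok(spec$effect)) {
    bad <- c(bad, "effect: must be in [0, 1]")
  }
  if (!is.finite(spec$per_person_cost) || spec$per_person_cost < 0) {
    bad <- c(bad, "per_person_cost: must be finite and >= 0")
  }
  if (length(bad)) {
    stop("invalid intervention spec:\n",
         paste0("  - ", bad, collapse = "\n"), call. = FALSE)
  }
  invisible(spec)
}
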