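#' @section Configuration schema:
#' A model run is described by a YAML file with these top-level keys
#' (required unless noted):
#'
#' * `entry_distribution`: `low`, `moderate`, `high`, `dead` proportions.
#' * `transitions`: `low_to_moderate`, `moderate_to_high`, `death_low`,
#'   `death_moderate`, `death_high` per-cycle probabilities.
#' * `costs`: `low`, `moderate`, `high`, `death_event` in GBP per cycle
#'   (death event one-off); optional `informal` sub-map (`low`,
#'   `moderate`, `high`) for the societal perspective.
#' * `utilities`: `low`, `moderate`, `high`, optional `dead` (must be 0),
#'   optional `decrement_schedule` list of `{age, decrement}` pairs
#'   (defaults to zero decrement at all ages).
#' * `settings` (optional): any argument of [model_settings()].
#' * `intervention` (optional): any argument of [intervention_spec()].
#' * `scenarios` (optional): grids for [run_scenario_suite()] — `effects`,
#'   `horizons`, `intervention_costs`, `subgroup_only`, `perspective`.
#'
#' Unknown top-level keys are reported as warnings, not errors.
#' @name config-format
NULL

required_config_keys <- c("entry_distribution", "transitions", "costs",
                          "utilities")
known_config_keys <- c(required_config_keys,
                       "settings", "intervention", "scenarios")

#' Load a model configuration
#'
#' Reads a YAML configuration (see [config-format]) into a
#' [model_parameters()] bundle, an optional [intervention_spec()], and an
#' optional scenario grid. The result round-trips through
#' [write_config()].
#'
#' @param path Path to a YAML configuration file.
#' @param validate Validate the bundle after loading (default `TRUE`).
#' @return A list with elements `params` ([model_parameters()]),
#'   `intervention` (or `NULL`) and `scenarios` (list or `NULL`).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "base_case.yaml",
#'                                package = "depcem"))
#' cfg$params$entry
load_config <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  missing <- setdiff(required_config_keys, names(raw))
  if (length(missing)) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), known_config_keys)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  need <- function(block, keys, where) {
    miss <- setdiff(keys, names(block))
    if (length(miss)) {
      stop(sprintf("config key '%s' is missing field(s): %s", where,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }

  ed <- raw$entry_distribution
  need(ed, dependence_levels(), "entry_distribution")
  entry <- state_distribution(ed$low, ed$moderate, ed$high, ed$dead)

  tr <- raw$transitions
  need(tr, c("low_to_moderate", "moderate_to_high", "death_low",
             "death_moderate", "death_high"), "transitions")
  transitions <- transition_model(tr$low_to_moderate, tr$moderate_to_high,
                                  tr$death_low, tr$death_moderate,
                                  tr$death_high)

  cs <- raw$costs
  need(cs, c(alive_levels(), "death_event"), "costs")
  informal <- NULL
  if (!is.null(cs$informal)) {
    need(cs$informal, alive_levels(), "costs$informal")
    informal <- c(low = cs$informal$low, moderate = cs$informal$moderate,
                  high = cs$informal$high)
  }
  costs <- cost_set(cs$low, cs$moderate, cs$high, cs$death_event,
                    informal = informal)

  ut <- raw$utilities
  need(ut, alive_levels(), "utilities")
  sched <- NULL
  if (!is.null(ut$decrement_schedule)) {
    sched <- do.call(rbind, lapply(ut$decrement_schedule, function(row) {
      data.frame(age = row$age, decrement = row$decrement)
    }))
  }
  utilities <- utility_set(ut$low, ut$moderate, ut$high,
                           dead = ut$dead %||% 0,
                           decrement_schedule = sched)

  settings <- do.call(model_settings,
                      raw$settings %||% list())
  params <- model_parameters(entry, transitions, costs, utilities, settings)
  if (validate) validate_parameters(params)

  intervention <- NULL
  if (!is.null(raw$intervention)) {
    intervention <- do.call(intervention_spec, raw$intervention)
  }

  list(params = params, intervention = intervention,
       scenarios = raw$scenarios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration
#'
#' Serialises a parameter bundle (and optionally an intervention and a
#' scenario grid) to the YAML layout read by [load_config()], so that
#' `load_config(write_config(...))` reproduces the bundle.
#'
#' @param params A [model_parameters()] bundle.
#' @param path Output file path.
#' @param intervention Optional [intervention_spec()].
#' @param scenarios Optional scenario-grid list.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, intervention = NULL,
                         scenarios = NULL) {
  u <- params$utilities
  s <- params$settings
  out <- list(
    entry_distribution = as.list(unclass(params$entry)),
    transitions = list(
      low_to_moderate = params$transitions$p_low_to_mod,
      moderate_to_high = params$transitions$p_mod_to_high,
      death_low = params$transitions$p_death_low,
      death_moderate = params$transitions$p_death_mod,
      death_high = params$transitions$p_death_high),
    costs = c(as.list(params$costs$care),
              list(death_event = params$costs$death_event),
              if (!is.null(params$costs$informal)) {
                list(informal = as.list(params$costs$informal))
              }),
    utilities = c(as.list(u$values), list(dead = u$dead),
                  if (!is.null(u$decrement_schedule)) {
                    list(decrement_schedule = lapply(
                      seq_len(nrow(u$decrement_schedule)), function(i) {
                        list(age = u$decrement_schedule$age[i],
                             decrement = u$decrement_schedule$decrement[i])
                      }))
                  }),
    settings = list(
      horizon_years = s$horizon_years,
      cycle_length_years = s$cycle_length_years,
      discount_rate_costs = s$discount_rate_costs,
      discount_rate_qalys = s$discount_rate_qalys,
      entry_age = s$entry_age,
      cohort_size = s$cohort_size,
      first_year_undiscounted = s$first_year_undiscounted,
      discount_method = s$discount_method,
      include_final_row = s$include_final_row,
      half_cycle_correction = s$half_cycle_correction,
      intervention_denominator = s$intervention_denominator)
  )
  if (!is.null(intervention)) {
    out$intervention <- list(
      effect = intervention$effect,
      per_person_cost = intervention$per_person_cost,
      subgroup_only = intervention$subgroup_only,
      mode = intervention$mode)
  }
  if (!is.null(scenarios)) out$scenarios <- scenarios
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Base-case model parameters
#'
#' The published base case: entry distribution 60/24/10/6
#' (low/moderate/high/dead), per-cycle progression probabilities 0.15
#' (low to moderate) and 0.07 (moderate to high), per-cycle death
#' probabilities 0.02/0.038/0.05, care costs 1738/3239/8510 GBP per
#' cycle, a 3519 GBP death admission, utilities 0.788/0.750/0.714, a
#' 10-year horizon of 3-month cycles, and 3.5% discounting beyond the
#' first year. Loaded from the packaged configuration file.
#'
#' @return A validated [model_parameters()] bundle.
#' @export
#' @examples
#' base_case_parameters()
base_case_parameters <- function() {
  path <- system.file("extdata", "base_case.yaml", package = "depcem")
  load_config(path)$params
}
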