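#' Build the per-cycle transition matrix
#'
#' Rows are from-states, columns to-states, in model order (low,
#' moderate, high, dead). Progression is stepwise and irreversible:
#' the only non-zero off-diagonal entries are low->moderate,
#' moderate->high, and each alive state's move to dead; dead is
#' absorbing.
#'
#' @param tm A [transition_model()].
#' @return A 4x4 matrix of class `"transition_matrix"` whose rows sum
#'   to 1.
#' @export
#' @examples
#' build_transition_matrix(transition_model(0.15, 0.07, 0.02, 0.038, 0.05))
build_transition_matrix <- function(tm) {
  stay_low <- 1 - tm$p_low_to_mod - tm$p_death_low
  stay_mod <- 1 - tm$p_mod_to_high - tm$p_death_mod
  stay_high <- 1 - tm$p_death_high
  if (stay_low < 0 || stay_mod < 0 || stay_high < 0) {
    stop("incompatible probabilities: a row's stay probability is negative",
         call. = FALSE)
  }
  m <- rbind(
    c(stay_low, tm$p_low_to_mod, 0, tm$p_death_low),
    c(0, stay_mod, tm$p_mod_to_high, tm$p_death_mod),
    c(0, 0, stay_high, tm$p_death_high),
    c(0, 0, 0, 1)
  )
  dimnames(m) <- list(dependence_levels(), dependence_levels())
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("transition matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Run the cohort through the model
#'
#' Propagates the (post-intervention) entry distribution through the
#' transition matrix for `n_cycles` cycles, recording occupancy at entry
#' and after every transition, plus the proportion newly entering the
#' dead state each cycle.
#'
#' @param entry A [state_distribution()].
#' @param matrix A [build_transition_matrix()] result.
#' @param settings A [model_settings()].
#' @return A `data.frame` of class `"cohort_trace"` with columns `cycle`
#'   (0..n_cycles), the four state occupancies, and `new_deaths`.
#' @export
#' @examples
#' p <- base_case_parameters()
#' tr <- run_cohort(p$entry, build_transition_matrix(p$transitions),
#'                  p$settings)
#' head(tr)
run_cohort <- function(entry, matrix, settings = model_settings()) {
  n <- as.integer(round(settings$n_cycles))
  occ <- matrix(0, n + 1L, 4L,
                dimnames = list(NULL, dependence_levels()))
  occ[1L, ] <- as.numeric(entry)
  for (t in seq_len(n)) {
    occ[t + 1L, ] <- occ[t, ] %*% matrix
  }
  out <- data.frame(cycle = 0:n, occ,
                    new_deaths = c(0, diff(occ[, "dead"])))
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Discount factor for a model cycle
#'
#' With `first_year_undiscounted = TRUE` (the base case), amounts accrued
#' in the first model year carry factor 1; later amounts are discounted
#' according to `settings$discount_method`:
#'
#' * `"one_step"` (calibrated default): one division by `1 + rate` for
#'   everything beyond the first year, regardless of how far beyond.
#' * `"annual"`: `(1 + rate)^-y`, `y` the completed-year index of the
#'   cycle (`floor(t * cycle_length_years)`).
#' * `"cycle"`: `(1 + rate)^-(t * cycle_length_years)`.
#'
#' With the flag off, `"one_step"` divides every amount once, and the
#' other two methods compound from time zero.
#'
#' @param t Cycle index (0-based), possibly vectorised.
#' @param annual_rate Annual discount rate (>= 0).
#' @param settings A [model_settings()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
#' @examples
#' s <- model_settings()
#' discount_factor(0:5, 0.035, s)
discount_factor <- function(t, annual_rate, settings = model_settings()) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  cl <- settings$cycle_length_years
  y <- floor(t * cl)
  first <- if (settings$first_year_undiscounted) y < 1 else rep(FALSE, length(t))
  f <- switch(settings$discount_method,
    one_step = rep(1 / (1 + annual_rate), length(t)),
    annual = (1 + annual_rate)^(-y),
    cycle = (1 + annual_rate)^(-(t * cl))
  )
  ifelse(first, 1, f)
}

# Accrual points, weights and occupancy/new-death rows for one run.
# Returns indices into the trace (1-based rows) and discount weights.
accrual_schedule <- function(trace, settings, annual_rate) {
  n <- nrow(trace) - 1L
  tt <- if (settings$include_final_row) 0:n else 0:(n - 1L)
  w <- discount_factor(tt, annual_rate, settings)
  if (settings$half_cycle_correction) {
    w[1L] <- w[1L] / 2
    w[length(w)] <- w[length(w)] / 2
  }
  list(rows = tt + 1L, weights = w)
}

#' Accumulate per-person costs over a cohort trace
#'
#' Sums, over accrual points `t`, the discounted per-person cost:
#' occupancy-weighted care costs of the alive states (plus informal-care
#' costs under the societal perspective), the death-event cost attached
#' to the proportion newly dying in cycle `t` (the proportion entering
#' dead at `t = 0` never incurs it), and the per-person intervention cost
#' charged undiscounted at entry. Occupancy at `t = 0` is the entry
#' distribution; for `t >= 1` it is the end-of-transition occupancy.
#' There is no half-cycle correction in the calibrated base case.
#'
#' @param trace A [run_cohort()] trace.
#' @param costs A [cost_set()].
#' @param intervention Optional [intervention_spec()]; its
#'   `per_person_cost` is charged at entry.
#' @param settings A [model_settings()].
#' @param perspective `"health_social_care"` (default) or `"societal"`
#'   (adds informal-care costs, which must be present in `costs`).
#' @param discount Set `FALSE` for the undiscounted total.
#' @return Cost in GBP per person (scalar).
#' @export
accumulate_costs <- function(trace, costs, intervention = NULL,
                             settings = model_settings(),
                             perspective = c("health_social_care",
                                             "societal"),
                             discount = TRUE) {
  perspective <- match.arg(perspective)
  per_state <- costs$care
  if (perspective == "societal") {
    if (is.null(costs$informal)) {
      stop("societal perspective requires informal-care costs", call. = FALSE)
    }
    per_state <- per_state + costs$informal
  }
  sched <- accrual_schedule(trace, settings,
                            if (discount) settings$discount_rate_costs else 0)
  w <- if (discount) sched$weights else {
    w0 <- rep(1, length(sched$rows))
    if (settings$half_cycle_correction) {
      w0[1L] <- 0.5; w0[length(w0)] <- 0.5
    }
    w0
  }
  occ <- as.matrix(trace[sched$rows, alive_levels()])
  cyc <- occ %*% per_state + trace$new_deaths[sched$rows] * costs$death_event
  total <- sum(w * cyc)
  if (!is.null(intervention)) {
    denom <- if (settings$intervention_denominator == "cohort") 1 else
      sum(trace[1L, alive_levels()])
    total <- total + intervention$per_person_cost * denom
  }
  as.numeric(total)
}

#' Accumulate per-person QALYs over a cohort trace
#'
#' Sums, over accrual points `t`, the discounted occupancy-weighted
#' utility of the alive states times the cycle length, with the
#' age-based utility decrement (if any) subtracted from every alive
#' state's utility at the cohort's age in that cycle (floored at zero).
#'
#' @param trace A [run_cohort()] trace.
#' @param utilities A [utility_set()].
#' @param settings A [model_settings()].
#' @param discount Set `FALSE` for the undiscounted total.
#' @return QALYs per person (scalar).
#' @export
accumulate_qalys <- function(trace, utilities,
                             settings = model_settings(),
                             discount = TRUE) {
  sched <- accrual_schedule(trace, settings,
                            if (discount) settings$discount_rate_qalys else 0)
  w <- if (discount) sched$weights else {
    w0 <- rep(1, length(sched$rows))
    if (settings$half_cycle_correction) {
      w0[1L] <- 0.5; w0[length(w0)] <- 0.5
    }
    w0
  }
  tt <- sched$rows - 1L
  age <- settings$entry_age + tt * settings$cycle_length_years
  dec <- decrement_at_age(utilities, age)
  if (any(dec < 0)) {
    stop("decrement schedule returned a negative decrement", call. = FALSE)
  }
  occ <- as.matrix(trace[sched$rows, alive_levels()])
  uu <- outer(dec, rep(1, 3))
  uu <- pmax(sweep(-uu, 2, utilities$values, `+`), 0)
  cyc <- rowSums(occ * uu) * settings$cycle_length_years
  as.numeric(sum(w * cyc))
}

#' Run the model for one cohort
#'
#' Applies the intervention effect (if any) to the entry distribution,
#' runs the cohort trace, and accumulates discounted and undiscounted
#' costs and QALYs.
#'
#' @param params A [model_parameters()] bundle.
#' @param intervention Optional [intervention_spec()]. Its entry-state
#'   effect and per-person cost are both applied; pass `NULL` for the
#'   no-intervention cohort.
#' @param perspective Costing perspective, see [accumulate_costs()].
#' @return A list of class `"person_level_result"`: `discounted_cost`,
#'   `discounted_qalys`, `undiscounted_cost`, `undiscounted_qalys`, the
#'   `trace`, and the `entry` distribution used.
#' @export
#' @examples
#' p <- base_case_parameters()
#' ctrl <- run_model(p)
#' round(ctrl$discounted_cost)
run_model <- function(params, intervention = NULL,
                      perspective = c("health_social_care", "societal")) {
  perspective <- match.arg(perspective)
  validate_parameters(params, perspective = perspective)
  entry <- params$entry
  if (!is.null(intervention)) {
    validate_intervention(intervention)
    entry <- apply_intervention_effect(entry, intervention$effect,
                                       subgroup_only = intervention$subgroup_only,
                                       mode = intervention$mode)
  }
  mat <- build_transition_matrix(params$transitions)
  trace <- run_cohort(entry, mat, params$settings)
  structure(
    list(discounted_cost = accumulate_costs(trace, params$costs, intervention,
                                            params$settings, perspective),
         discounted_qalys = accumulate_qalys(trace, params$utilities,
                                             params$settings),
         undiscounted_cost = accumulate_costs(trace, params$costs,
                                              intervention, params$settings,
                                              perspective, discount = FALSE),
         undiscounted_qalys = accumulate_qalys(trace, params$utilities,
                                               params$settings,
                                               discount = FALSE),
         trace = trace,
         entry = entry,
         perspective = perspective,
         intervention = intervention),
    class = "person_level_result"
  )
}

#' @export
print.person_level_result <- function(x, ...) {
  cat(sprintf("Per-person result (%s perspective)\n", x$perspective))
  cat(sprintf("  discounted:   cost GBP %s, QALYs %.3f\n",
              format(round(x$discounted_cost), big.mark = ","),
              x$discounted_qalys))
  cat(sprintf("  undiscounted: cost GBP %s, QALYs %.3f\n",
              format(round(x$undiscounted_cost), big.mark = ","),
              x$undiscounted_qalys))
  invisible(x)
}

#' Audit export of a cohort trace
#'
#' Cycle-by-cycle occupancy, new deaths, discount factors, and the
#' per-cycle cost and QALY contributions, for checking a run by hand.
#'
#' @param result A [run_model()] result.
#' @param params The [model_parameters()] used for the run.
#' @return A `data.frame`, one row per accrual point.
#' @export
trace_audit <- function(result, params) {
  trace <- result$trace
  s <- params$settings
  sched <- accrual_schedule(trace, s, s$discount_rate_costs)
  schedq <- accrual_schedule(trace, s, s$discount_rate_qalys)
  rows <- sched$rows
  occ <- as.matrix(trace[rows, alive_levels()])
  per_state <- params$costs$care
  if (result$perspective == "societal") per_state <- per_state + params$costs$informal
  cyc_cost <- occ %*% per_state +
    trace$new_deaths[rows] * params$costs$death_event
  tt <- rows - 1L
  age <- s$entry_age + tt * s$cycle_length_years
  dec <- decrement_at_age(params$utilities, age)
  uu <- pmax(sweep(-outer(dec, rep(1, 3)), 2, params$utilities$values, `+`), 0)
  cyc_q <- rowSums(occ * uu) * s$cycle_length_years
  data.frame(trace[rows, ],
             discount_cost = sched$weights,
             discount_qaly = schedq$weights,
             cycle_cost = as.numeric(cyc_cost),
             cycle_qalys = as.numeric(cyc_q),
             disc_cycle_cost = as.numeric(sched$weights * cyc_cost),
             disc_cycle_qalys = as.numeric(schedq$weights * cyc_q))
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n` individuals one-by-one through the same transition
#' matrix and accounting rules and returns the per-person mean cost and
#' QALYs with Monte-Carlo standard errors. Used to validate the cohort
#' trace: the cohort values must lie within a few standard errors of the
#' microsimulation means.
#'
#' @param params A [model_parameters()] bundle.
#' @param intervention Optional [intervention_spec()].
#' @param n Number of simulated individuals.
#' @param seed Optional integer seed (local to this call).
#' @param perspective Costing perspective.
#' @return A list with `mean_cost`, `mean_qalys`, `se_cost`, `se_qalys`,
#'   and `n`.
#' @export
run_microsim <- function(params, intervention = NULL, n = 100000,
                         seed = NULL,
                         perspective = c("health_social_care", "societal")) {
  perspective <- match.arg(perspective)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  s <- params$settings
  entry <- params$entry
  if (!is.null(intervention)) {
    entry <- apply_intervention_effect(entry, intervention$effect,
                                       subgroup_only = intervention$subgroup_only,
                                       mode = intervention$mode)
  }
  mat <- unclass(build_transition_matrix(params$transitions))
  cum <- t(apply(mat, 1, cumsum))
  n_cyc <- as.integer(round(s$n_cycles))

  state <- sample.int(4L, n, replace = TRUE, prob = as.numeric(entry))
  path <- matrix(0L, n, n_cyc + 1L)
  path[, 1L] <- state
  for (t in seq_len(n_cyc)) {
    u <- stats::runif(n)
    nxt <- 1L + (u > cum[state, 1L]) + (u > cum[state, 2L]) +
      (u > cum[state, 3L])
    path[, t + 1L] <- nxt
    state <- nxt
  }

  per_state_cost <- c(params$costs$care, 0)
  if (perspective == "societal") {
    if (is.null(params$costs$informal)) {
      stop("societal perspective requires informal-care costs", call. = FALSE)
    }
    per_state_cost <- per_state_cost + c(params$costs$informal, 0)
  }
  tt <- if (s$include_final_row) 0:n_cyc else 0:(n_cyc - 1L)
  wc <- discount_factor(tt, s$discount_rate_costs, s)
  wq <- discount_factor(tt, s$discount_rate_qalys, s)
  if (s$half_cycle_correction) {
    wc[1L] <- wc[1L] / 2; wc[length(wc)] <- wc[length(wc)] / 2
    wq[1L] <- wq[1L] / 2; wq[length(wq)] <- wq[length(wq)] / 2
  }
  age <- s$entry_age + tt * s$cycle_length_years
  dec <- decrement_at_age(params$utilities, age)
  umat <- pmax(sweep(-outer(dec, rep(1, 3)), 2, params$utilities$values, `+`), 0)
  umat <- cbind(umat, 0)  # dead column

  cost_i <- numeric(n)
  qaly_i <- numeric(n)
  for (k in seq_along(tt)) {
    st <- path[, tt[k] + 1L]
    cost_i <- cost_i + wc[k] * per_state_cost[st]
    qaly_i <- qaly_i + wq[k] * umat[k, st] * s$cycle_length_years
  }
  # death event: charged at the first cycle in which the person is dead,
  # having been alive the cycle before (dead-at-entry never pays it)
  died_at <- apply(path == 4L, 1L, function(z) {
    w <- which(z); if (length(w) && w[1L] > 1L) w[1L] else NA_integer_
  })
  has <- !is.na(died_at)
  wc_full <- discount_factor(0:n_cyc, s$discount_rate_costs, s)
  in_window <- has & (died_at - 1L) <= max(tt)
  cost_i[in_window] <- cost_i[in_window] +
    wc_full[died_at[in_window]] * params$costs$death_event
  if (!is.null(intervention)) {
    denom <- if (s$intervention_denominator == "cohort") 1 else
      sum(as.numeric(entry)[1:3])
    cost_i <- cost_i + intervention$per_person_cost * denom
  }
  list(mean_cost = mean(cost_i), mean_qalys = mean(qaly_i),
       se_cost = stats::sd(cost_i) / sqrt(n),
       se_qalys = stats::sd(qaly_i) / sqrt(n), n = n)
}
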