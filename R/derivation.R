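#' Categorise BADLS scores into dependence levels
#'
#' The Bristol Activities of Daily Living Scale total score (0-60, higher
#' means more dependent) is banded into the model's alive states:
#' low (0-14), moderate (15-29), high (30+).
#'
#' @param score Integer BADLS score(s) in `[0, 60]`.
#' @return Character vector of dependence levels (`"low"`, `"moderate"`,
#'   `"high"`).
#' @export
#' @examples
#' categorize_badls(c(0, 14, 15, 29, 30, 60))
categorize_badls <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 60) ||
      any(abs(score - round(score)) > 1e-9)) {
    stop("BADLS scores must be integers in [0, 60]", call. = FALSE)
  }
  ifelse(score <= 14, "low", ifelse(score <= 29, "moderate", "high"))
}

#' Convert an interval survival probability to a per-cycle death probability
#'
#' Under a constant-hazard assumption, a proportion `survival_prob`
#' surviving an interval of `interval_years` implies a per-cycle death
#' probability `1 - survival_prob^(cycle_length_years / interval_years)`.
#' This is how published interval survival (e.g. one-year survival by
#' dependence level) is converted to the model's 3-month clock.
#'
#' @param survival_prob Proportion surviving the interval, in `(0, 1]`.
#' @param interval_years Length of the source interval, years (> 0).
#' @param cycle_length_years Model cycle length, years (> 0).
#' @return Per-cycle probability of death.
#' @seealso [survival_from_death_prob()] for the inverse.
#' @export
#' @examples
#' death_prob_per_cycle(0.81450625, 1, 0.25)  # 0.05
death_prob_per_cycle <- function(survival_prob, interval_years,
                                 cycle_length_years = 0.25) {
  if (any(survival_prob <= 0) || any(survival_prob > 1)) {
    stop("survival_prob must be in (0, 1]", call. = FALSE)
  }
  if (any(interval_years <= 0) || any(cycle_length_years <= 0)) {
    stop("durations must be > 0", call. = FALSE)
  }
  1 - survival_prob^(cycle_length_years / interval_years)
}

#' Interval survival implied by a per-cycle death probability
#'
#' Inverse of [death_prob_per_cycle()]: the proportion surviving
#' `interval_years` when the per-cycle death probability is `p_cycle`.
#'
#' @param p_cycle Per-cycle death probability in `[0, 1)`.
#' @param interval_years Interval length, years (> 0).
#' @param cycle_length_years Model cycle length, years (> 0).
#' @return Survival proportion over the interval.
#' @export
#' @examples
#' survival_from_death_prob(0.05, 1, 0.25)  # 0.95^4
survival_from_death_prob <- function(p_cycle, interval_years,
                                     cycle_length_years = 0.25) {
  if (any(p_cycle < 0) || any(p_cycle >= 1)) {
    stop("p_cycle must be in [0, 1)", call. = FALSE)
  }
  if (any(interval_years <= 0) || any(cycle_length_years <= 0)) {
    stop("durations must be > 0", call. = FALSE)
  }
  (1 - p_cycle)^(interval_years / cycle_length_years)
}

#' Construct a longitudinal BADLS panel
#'
#' @param subject Subject identifiers.
#' @param month Assessment time in months from baseline (>= 0).
#' @param badls Integer BADLS score at the assessment.
#' @return A `data.frame` of class `"badls_panel"`, sorted by subject and
#'   time, with assessment times strictly increasing within subject.
#' @export
badls_panel <- function(subject, month, badls) {
  df <- data.frame(subject = as.character(subject),
                   month = as.numeric(month),
                   badls = as.numeric(badls))
  if (any(df$month < 0)) stop("assessment months must be >= 0", call. = FALSE)
  categorize_badls(df$badls)  # validates score range
  df <- df[order(df$subject, df$month), , drop = FALSE]
  if (anyDuplicated(df[c("subject", "month")])) {
    stop("duplicate (subject, month) assessment pairs", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("badls_panel", "data.frame")
  df
}

#' Read a BADLS panel from CSV
#'
#' Expects columns `subject`, `month`, `badls`.
#'
#' @param path CSV file path.
#' @return A [badls_panel()].
#' @export
read_badls_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "month", "badls")
  if (!all(need %in% names(df))) {
    stop("panel CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  badls_panel(df$subject, df$month, df$badls)
}

#' Estimate per-cycle progression probabilities from an irregular panel
#'
#' Reproduces the model's progression-parameter derivation from
#' longitudinal BADLS data observed at varying intervals. Each
#' consecutive within-subject assessment pair is classified by its start
#' state; a move to a higher dependence category is a transition event
#' (the model is irreversible, so observed backward moves count as
#' non-transitions and are tallied separately). Pairs are stratified by
#' interval length rounded to the nearest month; within each stratum the
#' empirical move proportion `p_d` over interval `d` months is rescaled
#' to the 3-month clock under constant hazard,
#' `p3 = 1 - (1 - p_d)^(cycle_length_months / d)`, and strata are combined
#' by an exposure-weighted average (weight = pairs x interval length).
#' A start-state pair whose end state skips a level (low at the start,
#' high at the end) counts as a progression event for the start state's
#' stratum and is also reported separately.
#'
#' @param panel A [badls_panel()].
#' @param cycle_length_months Target cycle length in months (default 3).
#' @return A list of class `"transition_estimate"` with elements
#'   `p_low_to_mod`, `p_mod_to_high`, per-stratum tables `strata_low` and
#'   `strata_mod` (interval, pairs, events, p3), and counts
#'   `backward_moves` and `skipped_level_pairs`.
#' @export
estimate_transitions <- function(panel, cycle_length_months = 3) {
  stopifnot(inherits(panel, "badls_panel"))
  state <- categorize_badls(panel$badls)
  rank <- match(state, alive_levels())

  sub <- panel$subject
  n <- nrow(panel)
  same <- n > 1 & sub[-n] == sub[-1]
  i1 <- which(same)
  if (!length(i1)) {
    stop("no eligible consecutive assessment pairs in panel", call. = FALSE)
  }
  i2 <- i1 + 1L
  interval <- round(panel$month[i2] - panel$month[i1])
  ok <- interval >= 1
  i1 <- i1[ok]; i2 <- i2[ok]; interval <- interval[ok]

  from <- rank[i1]
  to <- rank[i2]
  backward <- sum(to < from)
  skipped <- sum(from == 1 & to == 3)

  one_state <- function(from_rank) {
    sel <- from == from_rank
    if (!any(sel)) return(NULL)
    ivl <- interval[sel]
    event <- to[sel] > from_rank   # any move up, skipped levels included
    tab <- do.call(rbind, lapply(sort(unique(ivl)), function(d) {
      idx <- ivl == d
      p_d <- mean(event[idx])
      data.frame(interval = d, pairs = sum(idx), events = sum(event[idx]),
                 p3 = 1 - (1 - p_d)^(cycle_length_months / d))
    }))
    usable <- tab$p3 < 1  # p_d = 1 has unbounded hazard; drop with warning
    if (any(!usable)) {
      warning(sprintf(
        "dropping %d stratum/strata with all pairs transitioning (infinite hazard)",
        sum(!usable)), call. = FALSE)
      tab <- tab[usable, , drop = FALSE]
    }
    tab
  }

  res <- list()
  for (st in c("low", "moderate")) {
    tab <- one_state(match(st, alive_levels()))
    if (is.null(tab) || nrow(tab) == 0L) {
      warning(sprintf("no eligible pairs starting in %s; estimate omitted", st),
              call. = FALSE)
      res[[st]] <- list(p = NA_real_, tab = NULL)
    } else {
      w <- tab$pairs * tab$interval
      res[[st]] <- list(p = sum(w * tab$p3) / sum(w), tab = tab)
    }
  }
  if (all(is.na(c(res$low$p, res$moderate$p)))) {
    stop("no eligible pairs for any start state", call. = FALSE)
  }

  structure(
    list(p_low_to_mod = res$low$p,
         p_mod_to_high = res$moderate$p,
         strata_low = res$low$tab,
         strata_mod = res$moderate$tab,
         backward_moves = backward,
         skipped_level_pairs = skipped,
         n_pairs = length(i1),
         cycle_length_months = cycle_length_months),
    class = "transition_estimate"
  )
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("Per-%g-month progression probabilities from %d pairs\n",
              x$cycle_length_months, x$n_pairs))
  cat(sprintf("  low -> moderate: %.4f\n", x$p_low_to_mod))
  cat(sprintf("  moderate -> high: %.4f\n", x$p_mod_to_high))
  cat(sprintf("  backward moves (treated as non-transitions): %d\n",
              x$backward_moves))
  cat(sprintf("  skipped-level pairs (low at start, high at end): %d\n",
              x$skipped_level_pairs))
  invisible(x)
}

#' Estimate alive-state utilities from utility records
#'
#' Arithmetic mean of the utility index per dependence level, as used to
#' attach end-of-trial EQ-5D-5L index values to the model states.
#'
#' @param records `data.frame` with columns `state` (one of `"low"`,
#'   `"moderate"`, `"high"`) and `utility` (index value).
#' @return A [utility_set()] whose alive-state values are the per-state
#'   means, with per-state record counts in attribute `"n"`.
#' @export
#' @examples
#' rec <- data.frame(state = c("low", "moderate", "high"),
#'                   utility = c(0.788, 0.750, 0.714))
#' estimate_state_utilities(rec)$values
estimate_state_utilities <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("state", "utility") %in% names(records))) {
    stop("records must have columns 'state' and 'utility'", call. = FALSE)
  }
  if (any(records$state == "dead")) {
    stop("utility records must be for alive states only", call. = FALSE)
  }
  bad <- setdiff(unique(records$state), alive_levels())
  if (length(bad)) {
    stop("unknown state(s) in utility records: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(alive_levels(), unique(records$state))
  if (length(miss)) {
    stop("no utility records for state(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- tapply(records$utility, factor(records$state, alive_levels()), mean)
  n <- tapply(records$utility, factor(records$state, alive_levels()), length)
  out <- utility_set(m[["low"]], m[["moderate"]], m[["high"]])
  attr(out, "n") <- as.integer(n)
  out
}

#' Read utility records from CSV
#'
#' Expects columns `subject`, `state`, `utility`.
#'
#' @param path CSV file path.
#' @return A `data.frame` of utility records.
#' @export
read_utility_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "state", "utility")
  if (!all(need %in% names(df))) {
    stop("utility CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Export estimated parameters as a config fragment
#'
#' Builds the `transitions` and `utilities` blocks of the configuration
#' schema (see [config-format]) from estimation results, ready to merge
#' into a full model configuration.
#'
#' @param transitions Optional `"transition_estimate"` from
#'   [estimate_transitions()].
#' @param utilities Optional [utility_set()] (e.g. from
#'   [estimate_state_utilities()]).
#' @param mortality Optional named list with per-cycle death
#'   probabilities `death_low`, `death_moderate`, `death_high` (e.g. from
#'   [death_prob_per_cycle()]).
#' @param path Optional file; when given the fragment is written as YAML.
#' @return The fragment as a list, invisibly when `path` is given.
#' @export
config_fragment <- function(transitions = NULL, utilities = NULL,
                            mortality = NULL, path = NULL) {
  frag <- list()
  if (!is.null(transitions)) {
    frag$transitions <- list(
      low_to_moderate = transitions$p_low_to_mod,
      moderate_to_high = transitions$p_mod_to_high)
    if (!is.null(mortality)) {
      frag$transitions <- c(frag$transitions, mortality)
    }
  } else if (!is.null(mortality)) {
    frag$transitions <- mortality
  }
  if (!is.null(utilities)) {
    frag$utilities <- c(as.list(utilities$values), list(dead = utilities$dead))
  }
  if (!is.null(path)) {
    yaml::write_yaml(frag, path, precision = 15L)
    return(invisible(frag))
  }
  frag
}
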