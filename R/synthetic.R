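# Local seed handling: run code under a given seed without disturbing the
# caller's RNG stream; no seed means use the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  code
}

# Truncated-normal sampling with the post-truncation mean pinned to
# `mean`: truncation at the utility ceiling would otherwise bias the
# realised state means low, so the pre-truncation location is recentred.
trunc_norm_location <- function(mean, sd, lower, upper) {
  tn_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tn_mean(mu) - mean,
                 interval = c(lower, upper + 6 * sd),
                 tol = 1e-10)$root
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  mu <- trunc_norm_location(mean, sd, lower, upper)
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

badls_range <- function(state) {
  switch(state, low = c(0L, 14L), moderate = c(15L, 29L),
         high = c(30L, 60L))
}

#' Specification for a trial-like end-state cohort
#'
#' Describes a synthetic single-arm cohort observed at end of study, with
#' a target distribution over the four states, per-state mean utility
#' index values with common Gaussian noise (truncated to the valid index
#' range), and BADLS scores drawn uniformly within each state's band.
#' Defaults emulate the trial the base-case model entry distribution was
#' taken from: 354 participants distributed 60/24/10/6 across
#' low/moderate/high/dead with state utilities near 0.788/0.750/0.714.
#' The utility dispersion (0.15) is a generator choice, not an estimate
#' from any study.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param distribution Target end-of-study [state_distribution()].
#' @param utility_means Named utility means for the alive states.
#' @param utility_sd Common utility standard deviation (truncated to
#'   `utility_range`).
#' @param utility_range Valid utility index range.
#' @param allocation `"exact"` (default): state counts by largest
#'   remainder, so realised proportions match the target as closely as
#'   integers allow; `"multinomial"`: random allocation.
#' @param seed Optional integer seed.
#' @return A list of class `"trial_cohort_spec"`.
#' @export
trial_cohort_spec <- function(n_subjects = 354,
                              distribution = state_distribution(
                                0.60, 0.24, 0.10, 0.06),
                              utility_means = c(low = 0.788,
                                                moderate = 0.750,
                                                high = 0.714),
                              utility_sd = 0.15,
                              utility_range = c(-0.594, 1),
                              allocation = c("exact", "multinomial"),
                              seed = NULL) {
  if (n_subjects < 4) stop("n_subjects must be >= 4", call. = FALSE)
  if (abs(sum(distribution) - 1) > 1e-12 || any(distribution < 0)) {
    stop("target distribution must be a valid state distribution",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         distribution = distribution,
         utility_means = utility_means[alive_levels()],
         utility_sd = utility_sd,
         utility_range = utility_range,
         allocation = match.arg(allocation),
         seed = seed),
    class = "trial_cohort_spec"
  )
}

largest_remainder <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a trial-like end-state cohort
#'
#' Each subject is assigned an end-of-study state (exactly proportional
#' or multinomially, per the spec), a BADLS score drawn uniformly within
#' the state's band (so that [categorize_badls()] recovers the assigned
#' state exactly), and, for alive subjects, a utility index drawn from a
#' truncated normal around the state mean. Deterministic under a fixed
#' spec seed.
#'
#' @param spec A [trial_cohort_spec()].
#' @return A `data.frame` with columns `subject`, `state`, `dead`
#'   (logical), `badls` (`NA` for the dead), `utility` (`NA` for the
#'   dead).
#' @export
#' @examples
#' cohort <- generate_trial_cohort(trial_cohort_spec(n_subjects = 100,
#'                                                   seed = 1))
#' table(cohort$state)
generate_trial_cohort <- function(spec) {
  stopifnot(inherits(spec, "trial_cohort_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_subjects
    states <- dependence_levels()
    counts <- if (spec$allocation == "exact") {
      largest_remainder(n, as.numeric(spec$distribution))
    } else {
      as.integer(stats::rmultinom(1, n, as.numeric(spec$distribution)))
    }
    state <- rep(states, counts)
    badls <- rep(NA_integer_, n)
    utility <- rep(NA_real_, n)
    for (st in alive_levels()) {
      idx <- which(state == st)
      if (!length(idx)) next
      rng <- badls_range(st)
      badls[idx] <- sample(rng[1]:rng[2], length(idx), replace = TRUE)
      utility[idx] <- rtrunc_norm(length(idx), spec$utility_means[[st]],
                                  spec$utility_sd, spec$utility_range[1],
                                  spec$utility_range[2])
    }
    out <- data.frame(subject = sprintf("s%04d", seq_len(n)),
                      state = state, dead = state == "dead",
                      badls = badls, utility = utility)
    # shuffle so subject id carries no information about state
    out <- out[sample.int(n), , drop = FALSE]
    out$subject <- sprintf("s%04d", seq_len(n))
    rownames(out) <- NULL
    out
  })
}

#' Specification for a longitudinal BADLS panel
#'
#' Describes a synthetic panel emulating a multi-year longitudinal study
#' in which BADLS was collected at irregular intervals: each subject's
#' latent dependence state evolves forward-only in 3-month steps under a
#' true [transition_model()] (including death), and visits sample the
#' latent state at jittered intervals until dropout, death, or the end
#' of follow-up.
#'
#' @param n_subjects Number of subjects.
#' @param transitions True [transition_model()] generating the latent
#'   trajectories.
#' @param mean_interval_months Mean gap between visits, months.
#' @param jitter_months Visits are spaced uniformly in
#'   `mean_interval_months` plus or minus this jitter (rounded to whole
#'   months, minimum 1).
#' @param max_followup_months End of follow-up, months.
#' @param dropout_prob Probability a subject drops out after each visit.
#' @param seed Optional integer seed.
#' @return A list of class `"panel_spec"`.
#' @export
panel_spec <- function(n_subjects = 565,
                       transitions = transition_model(0.15, 0.07,
                                                      0.02, 0.038, 0.05),
                       mean_interval_months = 6,
                       jitter_months = 2,
                       max_followup_months = 55,
                       dropout_prob = 0.03,
                       seed = NULL) {
  if (mean_interval_months - jitter_months < 1) {
    stop("visit intervals must be at least 1 month", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         transitions = transitions,
         mean_interval_months = mean_interval_months,
         jitter_months = jitter_months,
         max_followup_months = max_followup_months,
         dropout_prob = dropout_prob,
         seed = seed),
    class = "panel_spec"
  )
}

#' Generate a longitudinal BADLS panel
#'
#' Subjects start at baseline in an alive state drawn from
#' `start_distribution`, so both progression strata accumulate
#' assessment pairs from the first visit on. The latent state advances in
#' 3-month steps under the spec's transition model; each visit reports a
#' BADLS score drawn uniformly within the current latent category's
#' band. Visits stop at death, dropout, or the end of follow-up.
#' Deterministic under a fixed spec seed.
#'
#' @param spec A [panel_spec()].
#' @param start_distribution Optional distribution over alive states for
#'   the baseline latent state (default: 50% low, 35% moderate, 15%
#'   high, a mild-to-moderate community cohort).
#' @return A [badls_panel()].
#' @export
#' @examples
#' panel <- generate_panel(panel_spec(n_subjects = 50, seed = 1))
#' head(panel)
generate_panel <- function(spec,
                           start_distribution = c(low = 0.50,
                                                  moderate = 0.35,
                                                  high = 0.15)) {
  stopifnot(inherits(spec, "panel_spec"))
  if (abs(sum(start_distribution) - 1) > 1e-9 || any(start_distribution < 0)) {
    stop("start_distribution must be a distribution over alive states",
         call. = FALSE)
  }
  tm <- spec$transitions
  step_mat <- unclass(build_transition_matrix(tm))
  cum <- t(apply(step_mat, 1, cumsum))
  with_local_seed(spec$seed, {
    n_steps <- floor(spec$max_followup_months / 3)
    n <- spec$n_subjects
    # latent paths, 3-month steps, states 1..4
    state <- sample.int(3L, n, replace = TRUE, prob = start_distribution)
    path <- matrix(0L, n, n_steps + 1L)
    path[, 1L] <- state
    for (k in seq_len(n_steps)) {
      u <- stats::runif(n)
      state <- 1L + (u > cum[state, 1L]) + (u > cum[state, 2L]) +
        (u > cum[state, 3L])
      path[, k + 1L] <- state
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      t_mo <- 0
      visits <- numeric(0)
      repeat {
        latent <- path[i, floor(t_mo / 3) + 1L]
        if (latent == 4L) break          # died before this visit
        visits <- c(visits, t_mo)
        if (stats::runif(1) < spec$dropout_prob) break
        gap <- round(stats::runif(1, spec$mean_interval_months -
                                    spec$jitter_months,
                                  spec$mean_interval_months +
                                    spec$jitter_months))
        gap <- max(1, gap)
        t_mo <- t_mo + gap
        if (t_mo > spec$max_followup_months) break
      }
      if (!length(visits)) next
      st <- path[i, floor(visits / 3) + 1L]
      sc <- vapply(st, function(s) {
        rng <- badls_range(alive_levels()[s])
        sample(rng[1]:rng[2], 1L)
      }, integer(1))
      rows[[i]] <- data.frame(subject = sprintf("p%05d", i),
                              month = visits, badls = sc)
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) stop("generated panel is empty", call. = FALSE)
    badls_panel(df$subject, df$month, df$badls)
  })
}

#' Write a synthetic dataset with a sidecar metadata file
#'
#' Writes the data as CSV and echoes the generating specification (and
#' seed) into `<path>.meta.yaml`, so any synthetic file is reproducible
#' from its sidecar alone.
#'
#' @param data A `data.frame` from one of the generators.
#' @param spec The generating spec.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(data, spec, path) {
  utils::write.csv(data, path, row.names = FALSE)
  meta <- lapply(unclass(spec), function(x) {
    if (inherits(x, "transition_model")) unclass(x)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  })
  meta$generator_class <- class(spec)[1]
  meta$package_version <- as.character(utils::packageVersion("depcem"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15L)
  invisible(path)
}
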