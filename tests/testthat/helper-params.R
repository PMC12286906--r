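# Base-case bundle built in code (independent of the packaged YAML).
base_params <- function(...) {
  model_parameters(
    entry = state_distribution(0.60, 0.24, 0.10, 0.06),
    transitions = transition_model(0.15, 0.07, 0.02, 0.038, 0.05),
    costs = cost_set(1738, 3239, 8510, death_event = 3519),
    utilities = utility_set(0.788, 0.750, 0.714),
    settings = model_settings(...)
  )
}

# Panel with a fixed number of consecutive-assessment pairs per stratum.
# movers of n_pairs subjects move up one level at the second visit,
# interval months apart.
two_visit_panel <- function(n_pairs, movers, start = "low",
                            interval = 3, offset = 0) {
  rng <- switch(start, low = c(0, 14), moderate = c(15, 29))
  up_rng <- switch(start, low = c(15, 29), moderate = c(30, 60))
  subject <- rep(sprintf("%s%04d", start, seq_len(n_pairs) + offset), each = 2)
  month <- rep(c(0, interval), n_pairs)
  badls <- as.vector(vapply(seq_len(n_pairs), function(i) {
    c(rng[1], if (i <= movers) up_rng[1] else rng[1])
  }, numeric(2)))
  badls_panel(subject, month, badls)
}
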