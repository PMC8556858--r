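## Small fixtures used across the unit tests. Populations, horizons and
## overdose rates are scaled so one test runs in seconds; event rates are
## sometimes inflated to get usable Monte-Carlo power at that scale.

tiny_profile <- function() {
  ring_profile(boundaries = c(0, 0.5, 1.5, Inf),
               visit_scale = c(1, 0.5, 0.1),
               population_proportion = c(0.5, 0.3, 0.2))
}

single_ring_profile <- function() {
  ring_profile(boundaries = c(0, Inf), visit_scale = 1,
               population_proportion = 1, base_visit_prob = 1)
}

params_with <- function(defaults, overrides) {
  defaults[names(overrides)] <- overrides
  do.call(ops_parameters, defaults)
}

fast_params <- function(...) {
  params_with(list(n_users_initial = 2000, horizon_days = 20,
                   new_entrants_per_day = 0), list(...))
}

## stress parameters: inflated overdose rates so small cohorts produce
## enough events for distributional comparisons
stress_params <- function(...) {
  params_with(list(n_users_initial = 500, horizon_days = 30,
                   annual_nonfatal_od = 0.5, annual_fatal_od = 0.1,
                   new_entrants_per_day = 1), list(...))
}
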