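#' Convert an annual probability to a per-step probability
#'
#' Uses the complement-compounding convention: the per-step probability `q`
#' satisfies `1 - (1 - q)^steps_per_year = p_annual`, so that compounding
#' the per-step hazard over a year reproduces the annual probability
#' exactly. (Simple division `p_annual / steps_per_year` agrees only to
#' first order; compounding is the convention that reproduces the published
#' equilibrium treatment population of nearly 13,000.)
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param steps_per_year Number of compounding steps per year (17,520 for
#'   30-minute steps).
#' @return Per-step probability.
#' @examples
#' q <- annual_to_step_prob(0.15, 17520)
#' 1 - (1 - q)^17520   # 0.15
#' @export
annual_to_step_prob <- function(p_annual, steps_per_year) {
  if (!is.numeric(p_annual) || any(is.na(p_annual)) ||
      any(p_annual < 0) || any(p_annual > 1))
    stop("p_annual must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(steps_per_year) || any(steps_per_year < 1))
    stop("steps_per_year must be >= 1", call. = FALSE)
  ## expm1/log1p formulation keeps full precision for tiny hazards
  -expm1(log1p(-p_annual) / steps_per_year)
}

#' Convert an annual overdose probability to a per-use probability
#'
#' Overdose hazard is attached to use events, not to elapsed time: the
#' per-use probability `r` satisfies `1 - (1 - r)^uses_per_year = annual_od`
#' with `uses_per_year = uses_per_day * 365` (1460 at the baseline of four
#' uses per day).
#'
#' @param annual_od Annual overdose probability in \[0, 1\].
#' @param uses_per_year Number of use events per year (>= 1).
#' @return Per-use overdose probability.
#' @examples
#' per_use_od_prob(0.069, 4 * 365)    # ~4.90e-5
#' per_use_od_prob(0.0188, 4 * 365)   # ~1.30e-5
#' @export
per_use_od_prob <- function(annual_od, uses_per_year) {
  if (!is.numeric(uses_per_year) || any(uses_per_year < 1))
    stop("uses_per_year must be >= 1", call. = FALSE)
  annual_to_step_prob(annual_od, uses_per_year)
}

#' Annual overdose rate implied by an event count and a population size
#'
#' @param count Number of overdose events observed in one year.
#' @param population Number of active opioid users (> 0).
#' @return The annual fraction `count / population`.
#' @examples
#' annual_od_fraction(3788, 55000)   # 0.0689 -> "6.9%"
#' annual_od_fraction(1033, 55000)   # 0.0188 -> "1.88%"
#' @export
annual_od_fraction <- function(count, population) {
  if (!is.numeric(population) || any(population <= 0))
    stop("population must be > 0", call. = FALSE)
  if (!is.numeric(count) || any(count < 0))
    stop("count must be nonnegative", call. = FALSE)
  count / population
}

#' Equilibrium number of users in treatment/recovery
#'
#' At the balance point, per-step inflow from the active population equals
#' per-step outflow by relapse: `T = active * q_in / q_out`, where `q_in`
#' and `q_out` are the per-step conversions of the annual entry and relapse
#' probabilities. In the small-step limit the ratio equals
#' `log(1 - annual_in) / log(1 - annual_out)`. With 55,000 active users,
#' 15%/yr entry and 50%/yr relapse this is about 12,896 ("nearly 13,000"),
#' and it is used to seed the treatment compartment.
#'
#' @param active Number of active users held at equilibrium.
#' @param annual_in Annual treatment-entry probability.
#' @param annual_out Annual relapse probability (> 0).
#' @param steps_per_year Compounding steps per year (default 17,520).
#' @return Expected equilibrium treatment/recovery population (real valued).
#' @examples
#' equilibrium_treatment_count(55000, 0.15, 0.50)  # ~12,896
#' @export
equilibrium_treatment_count <- function(active, annual_in, annual_out,
                                        steps_per_year = 17520) {
  if (!is.numeric(annual_out) || any(annual_out <= 0))
    stop("no equilibrium: annual_out must be > 0", call. = FALSE)
  q_in <- annual_to_step_prob(annual_in, steps_per_year)
  q_out <- annual_to_step_prob(annual_out, steps_per_year)
  active * q_in / q_out
}

#' Deterministic mean-field expectation of annual overdose events (no OPS)
#'
#' Iterates the expected-value recursion of the step dynamics over the
#' horizon with no random draws: at each step the expected number of users
#' initiating use, overdosing fatally/nonfatally, entering and leaving
#' treatment, and entering the population is propagated as a real-valued
#' state. Serves as the analytic oracle that the stochastic engine's
#' replicate means must bracket.
#'
#' @param params An [ops_parameters()] object with `ops_capacity = 0`.
#' @param init_treatment_entry Annual entry rate used to size the initial
#'   treatment compartment (defaults to the dynamic rate; scenario arms
#'   that raise the rate mid-study keep the baseline equilibrium here).
#' @return Named list with elements `fatal` and `nonfatal`: expected annual
#'   event counts.
#' @examples
#' ev <- expected_annual_events_no_ops(ops_parameters())
#' round(c(ev$fatal, ev$nonfatal))   # ~1044 and ~3934
#' @export
expected_annual_events_no_ops <- function(params,
                                          init_treatment_entry =
                                            params$annual_treatment_entry) {
  validate_parameters(params)
  if (params$ops_capacity != 0)
    stop("mean-field oracle is defined for the no-OPS model (ops_capacity = 0)",
         call. = FALSE)
  spd <- steps_per_day(params)
  spy <- steps_per_year(params)
  p_use <- params$uses_per_day / spd
  pf <- per_use_od_prob(params$annual_fatal_od, uses_per_year(params))
  pnf <- per_use_od_prob(params$annual_nonfatal_od, uses_per_year(params))
  q_t <- annual_to_step_prob(params$annual_treatment_entry, spy)
  q_r <- annual_to_step_prob(params$annual_relapse, spy)
  ent <- params$new_entrants_per_day / spd

  A <- params$n_users_initial
  Tr <- if (params$annual_relapse > 0 && params$n_users_initial > 0) {
    equilibrium_treatment_count(params$n_users_initial,
                                init_treatment_entry,
                                params$annual_relapse, spy)
  } else 0
  n_steps <- round(params$horizon_days * spd)
  fatal <- 0
  nonfatal <- 0
  for (s in seq_len(n_steps)) {
    using <- A * p_use
    f <- using * pf
    nf <- using * (1 - pf) * (pnf / (1 - pf))  # == using * pnf
    fatal <- fatal + f
    nonfatal <- nonfatal + nf
    ## survivors (incl. nonfatal ODs not referred) return to the active state
    A1 <- A - f - nf * params$od_referral_prob
    Tr <- Tr + nf * params$od_referral_prob
    tin <- A1 * q_t
    tout <- Tr * q_r
    A <- A1 - tin + tout + ent
    Tr <- Tr + tin - tout
  }
  list(fatal = fatal, nonfatal = nonfatal)
}
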