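#' Model parameters for the opioid-use / OPS simulation
#'
#' Bundles every scalar rate, count and overdose-prevention-site (OPS)
#' setting of the model, with the published Philadelphia baseline as the
#' default for each argument. All annual probabilities are converted
#' internally to per-step (30-minute) or per-use hazards; see
#' [annual_to_step_prob()] and [per_use_od_prob()].
#'
#' @param n_users_initial Number of active opioid users at the start of the
#'   simulated year (persons). Baseline 55,000.
#' @param annual_nonfatal_od Annual probability that an active user
#'   nonfatally overdoses. Baseline 0.069.
#' @param annual_fatal_od Annual probability that an active user fatally
#'   overdoses. Baseline 0.0188.
#' @param annual_treatment_entry Annual probability of entering
#'   treatment/recovery from the active (not-currently-using) state.
#'   Baseline 0.15.
#' @param annual_relapse Annual probability of leaving treatment/recovery
#'   and returning to active use. Baseline 0.50.
#' @param uses_per_day Mean number of drug-use events per active user per
#'   day; each use occupies one time step. Baseline 4.
#' @param step_minutes Length of one time step in minutes; must divide a day
#'   into an integer number of steps. Fixed at 30 in all reported analyses.
#' @param ops_capacity Number of simultaneous stations at the OPS; 0 means
#'   no OPS is present.
#' @param ops_hours_per_day Hours per day the OPS is open. Baseline 20.
#' @param ops_od_proportion Multiplier applied to the in-OPS per-use
#'   overdose probability, relative to the outside total (fatal + nonfatal)
#'   per-use rate. 1 means using in the OPS is exactly as risky as outside
#'   (every overdose is revived); values below 1 represent in-site safety
#'   measures such as drug checking and supervision.
#' @param ops_referral_prob Probability that a user who used at the OPS
#'   without overdosing is referred directly into treatment/recovery.
#'   Default 0.
#' @param od_referral_prob Probability that a survivor of a nonfatal
#'   overdose enters treatment/recovery instead of returning to the active
#'   state. Default 0.
#' @param new_entrants_per_day Mean number of new users entering the
#'   population per day (Poisson). Baseline 3.
#' @param horizon_days Length of one simulated replicate in days.
#'   Baseline 365.
#' @param n_replicates Default number of replicate simulations for
#'   experiment drivers.
#' @param base_visit_prob Probability that a user living within 0.25 miles
#'   of the OPS attempts to use there on a given use occasion. Baseline
#'   0.67; multiplied by the distance-ring visit scale farther out.
#'
#' @return An object of class `ops_parameters` (a validated named list).
#' @examples
#' p <- ops_parameters()              # published baseline
#' p30 <- ops_parameters(ops_capacity = 30)
#' steps_per_day(p)                   # 48
#' @export
ops_parameters <- function(n_users_initial = 55000,
                           annual_nonfatal_od = 0.069,
                           annual_fatal_od = 0.0188,
                           annual_treatment_entry = 0.15,
                           annual_relapse = 0.50,
                           uses_per_day = 4,
                           step_minutes = 30,
                           ops_capacity = 0,
                           ops_hours_per_day = 20,
                           ops_od_proportion = 1.0,
                           ops_referral_prob = 0,
                           od_referral_prob = 0,
                           new_entrants_per_day = 3,
                           horizon_days = 365,
                           n_replicates = 3000,
                           base_visit_prob = 0.67) {
  p <- list(
    n_users_initial = n_users_initial,
    annual_nonfatal_od = annual_nonfatal_od,
    annual_fatal_od = annual_fatal_od,
    annual_treatment_entry = annual_treatment_entry,
    annual_relapse = annual_relapse,
    uses_per_day = uses_per_day,
    step_minutes = step_minutes,
    ops_capacity = ops_capacity,
    ops_hours_per_day = ops_hours_per_day,
    ops_od_proportion = ops_od_proportion,
    ops_referral_prob = ops_referral_prob,
    od_referral_prob = od_referral_prob,
    new_entrants_per_day = new_entrants_per_day,
    horizon_days = horizon_days,
    n_replicates = n_replicates,
    base_visit_prob = base_visit_prob
  )
  class(p) <- "ops_parameters"
  validate_parameters(p)
  p
}

#' Validate an `ops_parameters` object
#'
#' Checks every type and range invariant of the parameter set and stops
#' with a message naming the offending field(s).
#'
#' @param p An `ops_parameters` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_parameters <- function(p) {
  bad <- character(0)
  chk_prob <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad <<- c(bad, sprintf("%s must be a probability in [0, 1]", name))
  }
  chk_nonneg <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      bad <<- c(bad, sprintf("%s must be a nonnegative number", name))
  }
  for (nm in c("annual_nonfatal_od", "annual_fatal_od",
               "annual_treatment_entry", "annual_relapse",
               "ops_referral_prob", "od_referral_prob", "base_visit_prob"))
    chk_prob(nm)
  for (nm in c("n_users_initial", "uses_per_day", "ops_capacity",
               "new_entrants_per_day", "horizon_days", "n_replicates"))
    chk_nonneg(nm)
  if (!is.numeric(p$ops_od_proportion) || p$ops_od_proportion < 0)
    bad <- c(bad, "ops_od_proportion must be nonnegative")
  if (!is.numeric(p$step_minutes) || p$step_minutes <= 0 ||
      (24 * 60) %% p$step_minutes != 0) {
    bad <- c(bad, "step_minutes must divide 24 h into an integer number of steps")
  } else {
    spd <- 24 * 60 / p$step_minutes
    if (p$uses_per_day > spd)
      bad <- c(bad, sprintf("uses_per_day (%s) exceeds steps per day (%s)",
                            p$uses_per_day, spd))
  }
  if (!is.numeric(p$ops_hours_per_day) || p$ops_hours_per_day < 0 ||
      p$ops_hours_per_day > 24)
    bad <- c(bad, "ops_hours_per_day must lie in [0, 24]")
  if (length(bad))
    stop("invalid model parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(p)
}

#' @rdname ops_parameters
#' @export
steps_per_day <- function(p) as.integer(24 * 60 / p$step_minutes)

#' @rdname ops_parameters
#' @export
steps_per_year <- function(p) steps_per_day(p) * 365L

#' @rdname ops_parameters
#' @export
uses_per_year <- function(p) p$uses_per_day * 365

#' Number of time steps per day during which the OPS is open
#' @param p An `ops_parameters` object.
#' @return Integer count of open steps (open hours start at midnight of the
#'   model day; under persistent saturation the placement of open hours
#'   within the day does not affect annual totals).
#' @export
ops_open_steps_per_day <- function(p) {
  as.integer(round(p$ops_hours_per_day * 60 / p$step_minutes))
}

#' @export
print.ops_parameters <- function(x, ...) {
  cat("Opioid-use / OPS model parameters\n")
  cat(sprintf("  active users (initial):   %s\n", format(x$n_users_initial, big.mark = ",")))
  cat(sprintf("  annual OD (nonfatal/fatal): %.4g / %.4g\n",
              x$annual_nonfatal_od, x$annual_fatal_od))
  cat(sprintf("  treatment entry / relapse (annual): %.3g / %.3g\n",
              x$annual_treatment_entry, x$annual_relapse))
  cat(sprintf("  uses per day: %g   step: %g min (%d steps/day)\n",
              x$uses_per_day, x$step_minutes, steps_per_day(x)))
  if (x$ops_capacity > 0) {
    cat(sprintf("  OPS: %d stations, %g h/day, OD proportion %.3g, referral %.3g\n",
                as.integer(x$ops_capacity), x$ops_hours_per_day,
                x$ops_od_proportion, x$ops_referral_prob))
  } else {
    cat("  OPS: none\n")
  }
  cat(sprintf("  new entrants: %g/day   horizon: %g days\n",
              x$new_entrants_per_day, x$horizon_days))
  invisible(x)
}
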