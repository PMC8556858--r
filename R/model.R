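#' Largest-remainder integer allocation
#'
#' Allocates `total` units across cells proportionally to `weights`,
#' rounding so the allocation sums to `total` exactly (floor everything,
#' then hand the remainder to the cells with the largest fractional parts;
#' ties broken by cell order).
#'
#' @param total Nonnegative integer total.
#' @param weights Nonnegative weights (need not sum to 1).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(total, weights) {
  if (total < 0 || any(weights < 0)) stop("negative input", call. = FALSE)
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Initial state of the simulation
#'
#' Allocates the initial active population across rings by the profile's
#' population proportions (largest-remainder rounding) and seeds the
#' treatment/recovery compartment at its equilibrium size (see
#' [equilibrium_treatment_count()]), allocated the same way. All event
#' counters start at zero.
#'
#' @param params An [ops_parameters()] object.
#' @param profile A [ring_profile()].
#' @param equilibrium_entry Annual treatment-entry probability used to size
#'   the initial treatment compartment; defaults to the value in `params`.
#'   Scenario sweeps that raise the treatment rate mid-study keep the
#'   baseline equilibrium here.
#' @return List with integer per-ring vectors `not_using` and `treatment`.
#' @export
initialize_state <- function(params, profile,
                             equilibrium_entry = params$annual_treatment_entry) {
  validate_parameters(params)
  treat_total <- if (params$annual_relapse > 0) {
    round(equilibrium_treatment_count(params$n_users_initial,
                                      equilibrium_entry,
                                      params$annual_relapse,
                                      steps_per_year(params)))
  } else 0
  list(not_using = largest_remainder(params$n_users_initial,
                                     profile$population_proportion),
       treatment = largest_remainder(treat_total,
                                     profile$population_proportion))
}

## Core engine: advances a whole batch of replicates simultaneously.
## Compartment counts are held as (replicate x ring) matrices and updated
## with vectorized binomial / hypergeometric / Poisson draws, which is
## exactly equivalent in distribution to independent per-agent chains
## (see simulate_year_microsim for the per-agent oracle).
##
## Per-step ordering, per ring:
##   1. NOT_USING -> initiate use (p_use = uses_per_day / steps_per_day);
##      initiators attempt the OPS with the ring's visit probability when
##      the site is open, otherwise use outside.
##   2. OPS admission up to capacity; the admitted subset is uniform over
##      attempters (multivariate hypergeometric across rings); the excess
##      uses outside in the same step.
##   3. Use resolution: outside -> fatal / nonfatal OD / return; in the OPS
##      -> nonfatal OD with probability ops_od_proportion * (p_f + p_nf),
##      never fatal; each in-OPS OD is tagged counterfactually fatal with
##      probability p_f / (p_f + p_nf) ("averted").
##   4. Nonfatal-OD resolution back to NOT_USING (or treatment with the
##      od_referral_prob knob).
##   5. Treatment entry / relapse hazards, both drawn from the
##      start-of-stage compartment sizes (parallel update).
##   6. Poisson new entrants into NOT_USING by ring proportion.
## Conservation (alive + cumulative fatal = initial + cumulative entrants)
## is asserted at every step.
##
## Revived tagging (common-random-numbers coupling with the no-OPS arm):
## a user whose in-OPS overdose is flagged counterfactually fatal moves to
## a "revived" copy of the active/treatment compartments. Tagged users
## follow exactly the same transition rules (so the run's own law is
## unchanged) but their subsequent events are recorded separately, because
## in the coupled no-OPS counterfactual those users are dead. The coupled
## baseline marginals are then, replicate by replicate,
##   fatal_no_ops    = fatal - tagged_fatal + averted
##   nonfatal_no_ops = nonfatal - tagged_nonfatal - averted
## which gives paired estimates of the direct effects with the shared
## event noise cancelled.
sim_batch <- function(params, profile, n_reps, seed,
                      init_treatment_entry = params$annual_treatment_entry) {
  validate_parameters(params)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  set.seed(seed)
  K <- n_rings(profile)
  R <- as.integer(n_reps)
  spd <- steps_per_day(params)
  spy <- steps_per_year(params)
  p_use <- params$uses_per_day / spd
  pf <- per_use_od_prob(params$annual_fatal_od, uses_per_year(params))
  pnf <- per_use_od_prob(params$annual_nonfatal_od, uses_per_year(params))
  pnf_cond <- if (pf < 1) pnf / (1 - pf) else 0
  p_ops_od <- min(1, params$ops_od_proportion * (pf + pnf))
  p_avert <- if (pf + pnf > 0) pf / (pf + pnf) else 0
  q_t <- annual_to_step_prob(params$annual_treatment_entry, spy)
  q_r <- annual_to_step_prob(params$annual_relapse, spy)
  vp <- rep(visit_probability(profile, seq_len(K)), each = R)
  lam <- rep(params$new_entrants_per_day / spd * profile$population_proportion,
             each = R)
  open_per_day <- ops_open_steps_per_day(params)
  cap <- as.integer(params$ops_capacity)
  n_steps <- as.integer(round(params$horizon_days * spd))

  init <- initialize_state(params, profile,
                           equilibrium_entry = init_treatment_entry)
  S1 <- matrix(rep(init$not_using, each = R), R, K)
  S4 <- matrix(rep(init$treatment, each = R), R, K)
  init_total <- sum(init$not_using) + sum(init$treatment)

  fatal <- nonfatal <- ops_od <- averted <- numeric(R)
  tagged_fatal <- tagged_nonfatal <- numeric(R)
  visits <- entrants <- occup <- numeric(R)
  open_steps_seen <- 0L
  revived <- matrix(0, R, K)
  RK <- R * K
  tagging <- cap > 0L           # revived compartments exist only with an OPS
  R1 <- R4 <- matrix(0, R, K)   # revived (tagged) active / treatment

  for (s in 0:(n_steps - 1L)) {
    open <- cap > 0L && (s %% spd) < open_per_day
    U <- rbinom(RK, S1, p_use); dim(U) <- c(R, K)
    S1 <- S1 - U
    UR <- NULL
    if (tagging) {
      UR <- rbinom(RK, R1, p_use); dim(UR) <- c(R, K)
      R1 <- R1 - UR
    }
    if (open) {
      A <- rbinom(RK, U, vp); dim(A) <- c(R, K)
      AR <- rbinom(RK, UR, vp); dim(AR) <- c(R, K)
      outside <- U - A
      outsideR <- UR - AR
      ## capacity allocation: uniform random subset of all attempters,
      ## jointly across rings and tags (multivariate hypergeometric)
      att <- cbind(A, AR)
      rest <- rowSums(att)
      adm_left <- pmin(cap, rest)
      X <- matrix(0, R, 2L * K)
      for (r in seq_len(2L * K)) {
        rest <- rest - att[, r]
        x <- rhyper(R, att[, r], rest, adm_left)
        X[, r] <- x
        adm_left <- adm_left - x
      }
      S3 <- X[, seq_len(K), drop = FALSE]
      S3R <- X[, K + seq_len(K), drop = FALSE]
      outside <- outside + (A - S3)
      outsideR <- outsideR + (AR - S3R)
    } else {
      outside <- U
      outsideR <- UR
    }
    ## outside use resolution (untagged)
    Fd <- rbinom(RK, outside, pf); dim(Fd) <- c(R, K)
    NFo <- rbinom(RK, outside - Fd, pnf_cond); dim(NFo) <- c(R, K)
    S1 <- S1 + (outside - Fd - NFo)
    fatal <- fatal + rowSums(Fd)
    nonfatal <- nonfatal + rowSums(NFo)
    od_pool <- NFo
    od_poolR <- NULL
    if (tagging) {
      ## outside use resolution (revived-tagged): same law, separate books
      FdR <- rbinom(RK, outsideR, pf); dim(FdR) <- c(R, K)
      NFoR <- rbinom(RK, outsideR - FdR, pnf_cond); dim(NFoR) <- c(R, K)
      R1 <- R1 + (outsideR - FdR - NFoR)
      fatal <- fatal + rowSums(FdR)
      tagged_fatal <- tagged_fatal + rowSums(FdR)
      nonfatal <- nonfatal + rowSums(NFoR)
      tagged_nonfatal <- tagged_nonfatal + rowSums(NFoR)
      od_poolR <- NFoR
    }
    if (open) {
      ODi <- rbinom(RK, S3, p_ops_od); dim(ODi) <- c(R, K)
      av <- rbinom(RK, ODi, p_avert); dim(av) <- c(R, K)
      ODr <- rbinom(RK, S3R, p_ops_od); dim(ODr) <- c(R, K)
      s3tot <- rowSums(S3) + rowSums(S3R)
      visits <- visits + s3tot
      occup <- occup + s3tot
      open_steps_seen <- open_steps_seen + 1L
      ops_od <- ops_od + rowSums(ODi) + rowSums(ODr)
      nonfatal <- nonfatal + rowSums(ODi) + rowSums(ODr)
      tagged_nonfatal <- tagged_nonfatal + rowSums(ODr)
      ## first-time counterfactual fatalities: tag and count as averted;
      ## in-OPS overdoses of already-tagged users are not averted again
      averted <- averted + rowSums(av)
      revived <- revived + av
      nonod <- S3 - ODi
      nonodR <- S3R - ODr
      if (params$ops_referral_prob > 0) {
        ref <- rbinom(RK, nonod, params$ops_referral_prob); dim(ref) <- c(R, K)
        S4 <- S4 + ref
        nonod <- nonod - ref
        refR <- rbinom(RK, nonodR, params$ops_referral_prob)
        dim(refR) <- c(R, K)
        R4 <- R4 + refR
        nonodR <- nonodR - refR
      }
      S1 <- S1 + nonod
      R1 <- R1 + nonodR
      od_pool <- od_pool + (ODi - av)
      od_poolR <- od_poolR + ODr + av
    }
    ## nonfatal-OD resolution
    if (params$od_referral_prob > 0) {
      refod <- rbinom(RK, od_pool, params$od_referral_prob)
      dim(refod) <- c(R, K)
      S4 <- S4 + refod
      od_pool <- od_pool - refod
      if (tagging) {
        refodR <- rbinom(RK, od_poolR, params$od_referral_prob)
        dim(refodR) <- c(R, K)
        R4 <- R4 + refodR
        od_poolR <- od_poolR - refodR
      }
    }
    S1 <- S1 + od_pool
    if (tagging) R1 <- R1 + od_poolR
    ## treatment entry / relapse (parallel on stage-start compartments)
    Tin <- rbinom(RK, S1, q_t); dim(Tin) <- c(R, K)
    Tout <- rbinom(RK, S4, q_r); dim(Tout) <- c(R, K)
    S1 <- S1 - Tin + Tout
    S4 <- S4 + Tin - Tout
    if (tagging) {
      TinR <- rbinom(RK, R1, q_t); dim(TinR) <- c(R, K)
      ToutR <- rbinom(RK, R4, q_r); dim(ToutR) <- c(R, K)
      R1 <- R1 - TinR + ToutR
      R4 <- R4 + TinR - ToutR
    }
    ## new entrants
    if (params$new_entrants_per_day > 0) {
      E <- rpois(RK, lam); dim(E) <- c(R, K)
      S1 <- S1 + E
      entrants <- entrants + rowSums(E)
    }
    alive <- rowSums(S1) + rowSums(S4) + rowSums(R1) + rowSums(R4)
    if (any(alive + fatal != init_total + entrants) || any(S1 < 0) ||
        any(S4 < 0) || any(R1 < 0) || any(R4 < 0))
      stop("internal consistency error: conservation violated at step ", s,
           call. = FALSE)
  }

  list(results = data.frame(
         replicate = seq_len(R),
         fatal = fatal,
         nonfatal = nonfatal,
         ops_od = ops_od,
         averted = averted,
         tagged_fatal = tagged_fatal,
         tagged_nonfatal = tagged_nonfatal,
         ops_visits = visits,
         entrants = entrants,
         mean_ops_occupancy = if (open_steps_seen > 0) occup / open_steps_seen
                              else rep(0, R),
         final_active = rowSums(S1) + rowSums(R1),
         final_treatment = rowSums(S4) + rowSums(R4)),
       revived = revived,
       seed = seed)
}

#' Simulate one year (one replicate)
#'
#' Runs the compartmental engine for one replicate of `horizon_days` days
#' (17,520 half-hour steps at the baseline horizon). Deterministic given
#' the seed.
#'
#' @param params An [ops_parameters()] object.
#' @param profile A [ring_profile()].
#' @param seed Integer seed.
#' @return A list of class `ops_sim_result` with annual `fatal`,
#'   `nonfatal` (including in-OPS overdoses) and `ops_od` event counts, the
#'   counterfactual `averted` tally, `ops_visits`, `entrants`,
#'   `mean_ops_occupancy` over open steps, a per-ring `revived` vector, and
#'   the `seed`.
#' @examples
#' prof <- ring_profile(c(0, 1, Inf), c(1, 0.1), c(0.5, 0.5))
#' p <- ops_parameters(n_users_initial = 500, horizon_days = 5)
#' simulate_year(p, prof, seed = 1)$fatal
#' @export
simulate_year <- function(params, profile, seed = 1) {
  b <- sim_batch(params, profile, n_reps = 1, seed = seed)
  r <- as.list(b$results[1, setdiff(names(b$results), "replicate")])
  r$revived <- as.numeric(b$revived[1, ])
  r$seed <- seed
  class(r) <- "ops_sim_result"
  r
}

#' Run replicate simulations and summarise them
#'
#' Runs `n_reps` independent one-year replicates (as a single vectorized
#' batch seeded by `seed`) and reports the replicate mean and Monte-Carlo
#' standard error (SD / sqrt(n)) of every result field.
#'
#' @inheritParams simulate_year
#' @param n_reps Number of replicates (the published analyses use 3000;
#'   a few hundred give standard errors of a few events per year).
#' @param init_treatment_entry Annual entry rate used to size the initial
#'   treatment compartment (see [initialize_state()]).
#' @return A list of class `ops_replicates`: `summary` (data frame of
#'   metric, mean, se), `replicates` (per-replicate data frame), `revived`
#'   (replicate x ring matrix of counterfactually-fatal overdoses revived
#'   in the OPS), `params`, `n_reps`, `seed`.
#' @export
run_replicates <- function(params, profile, n_reps = params$n_replicates,
                           seed = 1,
                           init_treatment_entry = params$annual_treatment_entry) {
  b <- sim_batch(params, profile, n_reps = n_reps, seed = seed,
                 init_treatment_entry = init_treatment_entry)
  metrics <- setdiff(names(b$results), "replicate")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(b$results[[m]]), numeric(1)),
    se = vapply(metrics, function(m) {
      stats::sd(b$results[[m]]) / sqrt(n_reps)
    }, numeric(1))
  )
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 replicates = b$results,
                 revived = b$revived,
                 params = params,
                 n_reps = as.integer(n_reps),
                 seed = seed),
            class = "ops_replicates")
}

#' Extract a summarised metric from an `ops_replicates` object
#' @param reps An `ops_replicates` object.
#' @param metric Metric name, e.g. `"fatal"`.
#' @param what `"mean"` or `"se"`.
#' @return Numeric scalar.
#' @export
replicate_stat <- function(reps, metric, what = "mean") {
  i <- match(metric, reps$summary$metric)
  if (is.na(i)) stop("unknown metric: ", metric, call. = FALSE)
  reps$summary[[what]][i]
}

#' @export
print.ops_replicates <- function(x, ...) {
  cat(sprintf("OPS simulation: %d replicates of %g days (seed %s)\n",
              x$n_reps, x$params$horizon_days, format(x$seed)))
  s <- x$summary
  s$mean <- signif(s$mean, 6)
  s$se <- signif(s$se, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Serialise replicate results
#'
#' Writes the per-replicate table as CSV and the summary (means, standard
#' errors, replicate count, seed) as JSON.
#'
#' @param reps An `ops_replicates` object.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of paths written.
#' @export
write_replicates <- function(reps, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(reps$replicates, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    out <- list(n_replicates = reps$n_reps, seed = reps$seed)
    for (i in seq_len(nrow(reps$summary))) {
      m <- reps$summary$metric[i]
      out[[paste0("mean_", m)]] <- reps$summary$mean[i]
      out[[paste0("se_", m)]] <- reps$summary$se[i]
    }
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
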