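## Scenario drivers. Each driver derives one child seed per scenario arm
## from the master seed so arms are independent and the whole experiment is
## reproducible from (master seed, replicate counts) alone.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 1e6) * 2053 + index * 7919) %% 2147483647L
}

#' No-OPS calibration experiment
#'
#' Replicate means of annual fatal and nonfatal overdose counts under the
#' baseline model with no OPS, the quantities benchmarked against the
#' observed Philadelphia year (1033 fatal / 3788 nonfatal reported; the
#' model's published prediction is 1045 / 3933).
#'
#' @param params An [ops_parameters()] object; `ops_capacity` is forced
#'   to 0.
#' @param profile A [ring_profile()]; defaults to the synthetic profile.
#' @param n_replicates Replicates (>= 300 recommended).
#' @param seed Master seed.
#' @return List with `mean_fatal`, `se_fatal`, `mean_nonfatal`,
#'   `se_nonfatal`, `n_replicates`, `seed` and the underlying
#'   `ops_replicates` object (`reps`).
#' @export
calibration_experiment <- function(params = ops_parameters(),
                                   profile = default_ring_profile(seed = seed),
                                   n_replicates = 300, seed = 1) {
  params$ops_capacity <- 0
  reps <- run_replicates(params, profile, n_reps = n_replicates,
                         seed = derive_seed(seed, 1))
  list(mean_fatal = replicate_stat(reps, "fatal"),
       se_fatal = replicate_stat(reps, "fatal", "se"),
       mean_nonfatal = replicate_stat(reps, "nonfatal"),
       se_nonfatal = replicate_stat(reps, "nonfatal", "se"),
       n_replicates = n_replicates,
       seed = seed,
       reps = reps)
}

#' Direct-effect capacity sweep
#'
#' Varies the OPS capacity (default 0 to 300 stations in steps of 30) with
#' the in-OPS overdose proportion fixed at 1, and reports per-capacity
#' replicate means, differences versus the no-OPS arm, and the fitted
#' least-squares slope of fatal reduction per 30 stations. Under baseline
#' demand the site is saturated whenever open, so the reduction is
#' approximately linear in capacity (about 6 averted fatalities per 30
#' stations).
#'
#' @inheritParams calibration_experiment
#' @param capacities Capacities to sweep; 0 is prepended if absent.
#' @param n_replicates Replicates per nonzero-capacity arm.
#' @param baseline_replicates Replicates for the no-OPS arm (defaults to
#'   twice `n_replicates`; the baseline enters every difference).
#' @return List of class `ops_capacity_sweep`: `table` (one row per
#'   capacity with means, SEs, differences vs capacity 0), `slope_per_30`,
#'   `slope_se_per_30`, `seed`.
#' @export
capacity_sweep <- function(params = ops_parameters(),
                           profile = default_ring_profile(seed = seed),
                           capacities = seq(0, 300, by = 30),
                           n_replicates = 100,
                           baseline_replicates = 2L * n_replicates,
                           seed = 1) {
  if (!0 %in% capacities) capacities <- c(0, capacities)
  capacities <- sort(unique(capacities))
  params$ops_od_proportion <- 1
  arms <- lapply(seq_along(capacities), function(i) {
    p <- params
    p$ops_capacity <- capacities[i]
    run_replicates(p, profile,
                   n_reps = if (capacities[i] == 0) baseline_replicates
                            else n_replicates,
                   seed = derive_seed(seed, i))
  })
  mf <- vapply(arms, replicate_stat, numeric(1), metric = "fatal")
  sf <- vapply(arms, replicate_stat, numeric(1), metric = "fatal", what = "se")
  mn <- vapply(arms, replicate_stat, numeric(1), metric = "nonfatal")
  sn <- vapply(arms, replicate_stat, numeric(1), metric = "nonfatal",
               what = "se")
  mav <- vapply(arms, replicate_stat, numeric(1), metric = "averted")
  i0 <- which(capacities == 0)
  tab <- data.frame(
    capacity = capacities,
    n_reps = vapply(arms, function(a) a$n_reps, integer(1)),
    mean_fatal = mf, se_fatal = sf,
    mean_nonfatal = mn, se_nonfatal = sn,
    mean_averted_tagged = mav,
    fatal_reduction = mf[i0] - mf,
    fatal_reduction_se = ifelse(capacities == 0, 0, sqrt(sf^2 + sf[i0]^2)),
    nonfatal_change = mn - mn[i0],
    nonfatal_change_se = ifelse(capacities == 0, 0, sqrt(sn^2 + sn[i0]^2))
  )
  fit <- stats::lm(fatal_reduction ~ capacity, data = tab)
  slope <- unname(stats::coef(fit)["capacity"])
  slope_se <- summary(fit)$coefficients["capacity", "Std. Error"]
  structure(list(table = tab,
                 slope_per_30 = 30 * slope,
                 slope_se_per_30 = 30 * slope_se,
                 arms = arms,
                 seed = seed),
            class = "ops_capacity_sweep")
}

#' Analytic break-even proportion
#'
#' The in-OPS overdose proportion at which the extra nonfatal overdoses
#' created by reviving would-be fatalities exactly offset the nonfatal
#' overdoses displaced from the street: under site saturation the net
#' nonfatal change is `visits * (proportion * (p_f + p_nf) - p_nf)`, which
#' crosses zero at `p_nf / (p_f + p_nf)` independent of capacity.
#'
#' @param params An [ops_parameters()] object.
#' @return The break-even proportion (about 0.79 at baseline rates, i.e. a
#'   ~21% reduction of the in-OPS overdose rate).
#' @export
breakeven_proportion_analytic <- function(params = ops_parameters()) {
  pf <- per_use_od_prob(params$annual_fatal_od, uses_per_year(params))
  pnf <- per_use_od_prob(params$annual_nonfatal_od, uses_per_year(params))
  pnf / (pf + pnf)
}

#' In-OPS overdose-proportion sweep with break-even search
#'
#' For each capacity, locates the in-OPS overdose proportion at which the
#' net change in annual nonfatal overdoses (versus no OPS) crosses zero,
#' by linear interpolation on a proportion grid. Reported as
#' `reduction = 1 - proportion` (published band: 20-30% for every capacity
#' between 30 and 300).
#'
#' Two estimators are available. `"paired"` (default) exploits the fact
#' that with no treatment referral the in-OPS overdose outcome does not
#' feed back on the trajectory: one proportion-1 run per capacity is
#' performed, and every proportion on the grid is evaluated on the shared
#' trajectory by exact binomial thinning of the recorded in-OPS overdose
#' events, against the in-run counterfactual (the same uses resolved at
#' street rates). This is the maximal common-random-numbers coupling and
#' reduces the Monte-Carlo error of the crossing by roughly two orders of
#' magnitude; it neglects only the survivor-feedback term (extra overdoses
#' among revived users), which shifts the crossing by under one percentage
#' point. `"independent"` runs a separate batch for every (capacity,
#' proportion) cell and differences replicate means against a no-OPS arm,
#' as the published sweep figures were computed; at small capacities it
#' needs thousands of replicates to resolve the crossing.
#'
#' @inheritParams calibration_experiment
#' @param proportions Proportion grid in (0, 1].
#' @param capacities Capacities (> 0) to sweep.
#' @param n_replicates Replicates per capacity (paired) or per cell
#'   (independent).
#' @param method `"paired"` or `"independent"`.
#' @return List of class `ops_proportion_sweep`: `surface` (capacity x
#'   proportion grid of mean net nonfatal change and SE), `breakeven`
#'   (per-capacity crossing proportion, reduction, and SE; `NA` when not
#'   bracketed by the grid), `analytic` (the saturation value), `method`,
#'   `seed`.
#' @export
proportion_sweep <- function(params = ops_parameters(),
                             profile = default_ring_profile(seed = seed),
                             proportions = seq(0.5, 1, by = 0.05),
                             capacities = seq(30, 300, by = 30),
                             n_replicates = 60,
                             seed = 1,
                             method = c("paired", "independent")) {
  method <- match.arg(method)
  if (any(proportions <= 0) || any(proportions > 1))
    stop("proportions must lie in (0, 1]", call. = FALSE)
  if (any(capacities <= 0))
    stop("capacities must be positive for the proportion sweep", call. = FALSE)
  proportions <- sort(proportions)
  surface <- list()
  if (method == "paired") {
    for (i in seq_along(capacities)) {
      p <- params
      p$ops_capacity <- capacities[i]
      p$ops_od_proportion <- 1
      reps <- run_replicates(p, profile, n_reps = n_replicates,
                             seed = derive_seed(seed, i))
      od1 <- reps$replicates$ops_od          # in-OPS ODs at proportion 1
      cf_nf <- od1 - reps$replicates$averted # would-be street nonfatal ODs
      ## nested thinning: one uniform per proportion-1 event; the events
      ## retained at proportion p are those with u <= p, so all grid points
      ## share the same event-level randomness
      u <- stats::runif(sum(od1))
      rep_id <- rep(seq_along(od1), od1)
      change <- vapply(proportions, function(pr) {
        odp <- tabulate(rep_id[u <= pr], nbins = length(od1))
        ch <- odp - cf_nf
        c(mean(ch), stats::sd(ch) / sqrt(length(ch)))
      }, numeric(2))
      surface[[i]] <- data.frame(capacity = capacities[i],
                                 proportion = proportions,
                                 mean_change = change[1, ],
                                 se_change = change[2, ])
    }
  } else {
    p0 <- params
    p0$ops_capacity <- 0
    base <- run_replicates(p0, profile, n_reps = n_replicates,
                           seed = derive_seed(seed, 0))
    b_mean <- replicate_stat(base, "nonfatal")
    b_se <- replicate_stat(base, "nonfatal", "se")
    k <- 0
    for (i in seq_along(capacities)) {
      rows <- lapply(seq_along(proportions), function(j) {
        k <<- k + 1
        p <- params
        p$ops_capacity <- capacities[i]
        p$ops_od_proportion <- proportions[j]
        reps <- run_replicates(p, profile, n_reps = n_replicates,
                               seed = derive_seed(seed, 100 + k))
        data.frame(capacity = capacities[i],
                   proportion = proportions[j],
                   mean_change = replicate_stat(reps, "nonfatal") - b_mean,
                   se_change = sqrt(replicate_stat(reps, "nonfatal", "se")^2 +
                                      b_se^2))
      })
      surface[[i]] <- do.call(rbind, rows)
    }
  }
  surface <- do.call(rbind, surface)

  breakeven <- do.call(rbind, lapply(capacities, function(cp) {
    s <- surface[surface$capacity == cp, ]
    m <- s$mean_change
    cross <- which(m[-length(m)] * m[-1] <= 0 &
                     (m[-length(m)] != 0 | m[-1] != 0))
    if (length(cross) == 0) {
      return(data.frame(capacity = cp, proportion_at_zero = NA_real_,
                        reduction = NA_real_, se = NA_real_,
                        bracketed = FALSE))
    }
    j <- cross[1]
    p1 <- s$proportion[j]; p2 <- s$proportion[j + 1]
    m1 <- m[j]; m2 <- m[j + 1]
    pstar <- p1 + (0 - m1) * (p2 - p1) / (m2 - m1)
    slope <- (m2 - m1) / (p2 - p1)
    se <- mean(s$se_change[c(j, j + 1)]) / abs(slope)
    data.frame(capacity = cp, proportion_at_zero = pstar,
               reduction = 1 - pstar, se = se, bracketed = TRUE)
  }))

  structure(list(surface = surface,
                 breakeven = breakeven,
                 analytic = breakeven_proportion_analytic(params),
                 method = method,
                 seed = seed),
            class = "ops_proportion_sweep")
}

#' Population treatment-rate sweep
#'
#' Raises the population-wide annual treatment-entry rate (relapse held at
#' its baseline) and reports replicate-mean differences in annual fatal
#' and nonfatal overdoses versus the first (baseline) rate. All arms start
#' from the same initial conditions, with the treatment compartment at the
#' equilibrium of `init_rate` (the baseline 15%): the sweep measures the
#' one-year response to raising the rate, not a new steady state.
#'
#' @inheritParams calibration_experiment
#' @param rates Annual treatment-entry rates; the first is the baseline
#'   arm.
#' @param init_rate Rate defining the shared initial treatment equilibrium.
#' @param pairing `"crn"` (default) simulates each raised arm jointly with
#'   the baseline arm as a coupled chain ([treatment_pair_crn()]), so the
#'   shared event noise cancels in the reported reductions;
#'   `"independent"` differences separately simulated arms. Pairing never
#'   changes the expected differences, only their Monte-Carlo error.
#' @return List of class `ops_treatment_sweep` with `table` (one row per
#'   rate: means, SEs, reductions vs baseline with SEs), `pairing` and
#'   `seed`.
#' @export
treatment_sweep <- function(params = ops_parameters(),
                            profile = default_ring_profile(seed = seed),
                            rates = c(0.15, 0.20, 0.25),
                            n_replicates = 300,
                            seed = 1,
                            init_rate = rates[1],
                            pairing = c("crn", "independent")) {
  pairing <- match.arg(pairing)
  if (length(rates) < 1) stop("need at least one rate", call. = FALSE)
  if (any(diff(rates) < 0) || any(rates < rates[1]))
    rates <- sort(rates)
  mc_se <- function(x) stats::sd(x) / sqrt(length(x))
  if (pairing == "crn") {
    base_rate <- rates[1]
    pairs <- lapply(seq_along(rates)[-1], function(i) {
      p <- params
      p$ops_capacity <- 0
      treatment_pair_crn(p, base_rate, rates[i], n_reps = n_replicates,
                         seed = derive_seed(seed, i), init_rate = init_rate)
    })
    ## baseline row from the first pair's arm-A marginal (or its own run
    ## when the sweep has a single rate)
    if (length(pairs)) {
      base_f <- pairs[[1]]$fatal_a
      base_n <- pairs[[1]]$nonfatal_a
    } else {
      p <- params
      p$annual_treatment_entry <- base_rate
      r <- run_replicates(p, profile, n_reps = n_replicates,
                          seed = derive_seed(seed, 1),
                          init_treatment_entry = init_rate)
      base_f <- r$replicates$fatal
      base_n <- r$replicates$nonfatal
    }
    mf <- c(mean(base_f), vapply(pairs, function(d) mean(d$fatal_b), numeric(1)))
    sf <- c(mc_se(base_f), vapply(pairs, function(d) mc_se(d$fatal_b), numeric(1)))
    mn <- c(mean(base_n), vapply(pairs, function(d) mean(d$nonfatal_b), numeric(1)))
    sn <- c(mc_se(base_n), vapply(pairs, function(d) mc_se(d$nonfatal_b), numeric(1)))
    fr <- c(0, vapply(pairs, function(d) mean(d$fatal_reduction), numeric(1)))
    frse <- c(0, vapply(pairs, function(d) mc_se(d$fatal_reduction), numeric(1)))
    nr <- c(0, vapply(pairs, function(d) mean(d$nonfatal_reduction), numeric(1)))
    nrse <- c(0, vapply(pairs, function(d) mc_se(d$nonfatal_reduction), numeric(1)))
  } else {
    arms <- lapply(seq_along(rates), function(i) {
      p <- params
      p$annual_treatment_entry <- rates[i]
      run_replicates(p, profile, n_reps = n_replicates,
                     seed = derive_seed(seed, i),
                     init_treatment_entry = init_rate)
    })
    mf <- vapply(arms, replicate_stat, numeric(1), metric = "fatal")
    sf <- vapply(arms, replicate_stat, numeric(1), metric = "fatal", what = "se")
    mn <- vapply(arms, replicate_stat, numeric(1), metric = "nonfatal")
    sn <- vapply(arms, replicate_stat, numeric(1), metric = "nonfatal",
                 what = "se")
    fr <- mf[1] - mf
    frse <- ifelse(seq_along(rates) == 1, 0, sqrt(sf^2 + sf[1]^2))
    nr <- mn[1] - mn
    nrse <- ifelse(seq_along(rates) == 1, 0, sqrt(sn^2 + sn[1]^2))
  }
  tab <- data.frame(
    rate = rates,
    n_reps = n_replicates,
    mean_fatal = mf, se_fatal = sf,
    mean_nonfatal = mn, se_nonfatal = sn,
    fatal_reduction = fr,
    fatal_reduction_se = frse,
    nonfatal_reduction = nr,
    nonfatal_reduction_se = nrse
  )
  structure(list(table = tab, pairing = pairing, seed = seed),
            class = "ops_treatment_sweep")
}

#' Spatial attribution of in-OPS revivals
#'
#' Distributes the counterfactually-fatal overdoses revived in the OPS
#' across distance rings and reports cumulative revived shares at 1 and
#' 1.5 miles next to the corresponding population shares. Because the
#' visit probability decays with distance, revivals concentrate near the
#' site: the revived share within any radius is at least the population
#' share (published simulations: 74% of revivals within 1 mile vs 30% of
#' users; 86% within 1.5 miles vs 38%).
#'
#' @param reps An `ops_replicates` object from a run with
#'   `ops_capacity > 0`.
#' @param profile The [ring_profile()] used for the run.
#' @return List with `per_ring` (data frame of revived counts and shares
#'   next to population proportions) and `cumulative` (data frame of
#'   cumulative revived vs population share at each finite ring boundary).
#'   Shares are `NA` with a message when no revivals occurred.
#' @export
spatial_attribution <- function(reps, profile) {
  rv <- colSums(reps$revived)
  k <- n_rings(profile)
  tot <- sum(rv)
  share <- if (tot > 0) rv / tot else rep(NA_real_, k)
  if (tot == 0) message("no revivals recorded; shares undefined")
  per_ring <- data.frame(
    ring_lo_miles = profile$boundaries[seq_len(k)],
    ring_hi_miles = profile$boundaries[seq_len(k) + 1],
    revived = rv,
    revived_share = share,
    population_proportion = profile$population_proportion
  )
  bnd <- profile$boundaries[-1]
  fin <- is.finite(bnd)
  cumulative <- data.frame(
    distance_miles = bnd[fin],
    revived_share = cumsum(share)[fin],
    population_share = cumsum(profile$population_proportion)[fin]
  )
  list(per_ring = per_ring, cumulative = cumulative)
}
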