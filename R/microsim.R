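#' Per-agent microsimulation oracle
#'
#' Simulates individual agents with exactly the per-agent transition rules
#' that the compartmental engine applies in aggregate: per-step Bernoulli
#' use initiation, distance-dependent OPS attempts, uniform admission of a
#' capacity-limited subset, per-use overdose resolution (never fatal in the
#' OPS), treatment entry/relapse hazards, and Poisson entrants. Because a
#' sum of independent Bernoulli draws is binomial and a uniformly chosen
#' admitted subset is hypergeometric across rings, the two engines have
#' identical event distributions; this function exists to prove that on
#' small populations, and is not intended for production-scale runs.
#'
#' @inheritParams simulate_year
#' @param n_agents Initial active agents (allocated across rings by the
#'   profile proportions; the treatment compartment is seeded at its
#'   equilibrium share of `n_agents`). Keep small (<= ~2000).
#' @return A list of class `ops_sim_result` with the same fields as
#'   [simulate_year()].
#' @export
simulate_year_microsim <- function(params, profile, seed = 1,
                                   n_agents = params$n_users_initial) {
  validate_parameters(params)
  set.seed(seed)
  K <- n_rings(profile)
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
  vp <- visit_probability(profile, seq_len(K))
  open_per_day <- ops_open_steps_per_day(params)
  cap <- as.integer(params$ops_capacity)
  ent_rate <- params$new_entrants_per_day / spd
  n_steps <- as.integer(round(params$horizon_days * spd))

  p2 <- params
  p2$n_users_initial <- n_agents
  init <- initialize_state(p2, profile)
  rg <- c(rep(seq_len(K), init$not_using), rep(seq_len(K), init$treatment))
  st <- c(rep(1L, sum(init$not_using)), rep(4L, sum(init$treatment)))
  init_total <- length(st)

  fatal <- nonfatal <- ops_odc <- avertedc <- visits <- entrantsc <- 0
  occup <- 0; open_steps_seen <- 0L
  revived <- numeric(K)

  for (s in 0:(n_steps - 1L)) {
    open <- cap > 0L && (s %% spd) < open_per_day
    a1 <- which(st == 1L)
    use <- a1[stats::runif(length(a1)) < p_use]
    if (open && length(use)) {
      att <- use[stats::runif(length(use)) < vp[rg[use]]]
      adm <- if (length(att) > cap) sample(att, cap) else att
      outside <- setdiff(use, adm)
    } else {
      adm <- integer(0)
      outside <- use
    }
    od_idx <- integer(0)
    if (length(outside)) {
      u <- stats::runif(length(outside))
      dead <- outside[u < pf]
      nfod <- outside[u >= pf & u < pf + pnf]
      st[dead] <- 6L
      fatal <- fatal + length(dead)
      nonfatal <- nonfatal + length(nfod)
      od_idx <- nfod
    }
    if (length(adm)) {
      visits <- visits + length(adm)
      occup <- occup + length(adm)
      odo <- adm[stats::runif(length(adm)) < p_ops_od]
      ops_odc <- ops_odc + length(odo)
      nonfatal <- nonfatal + length(odo)
      avo <- odo[stats::runif(length(odo)) < p_avert]
      avertedc <- avertedc + length(avo)
      if (length(avo))
        revived <- revived + tabulate(rg[avo], nbins = K)
      nonod <- setdiff(adm, odo)
      if (params$ops_referral_prob > 0 && length(nonod)) {
        ref <- nonod[stats::runif(length(nonod)) < params$ops_referral_prob]
        st[ref] <- 4L
      }
      od_idx <- c(od_idx, odo)
    }
    if (open) open_steps_seen <- open_steps_seen + 1L
    if (params$od_referral_prob > 0 && length(od_idx)) {
      ref <- od_idx[stats::runif(length(od_idx)) < params$od_referral_prob]
      st[ref] <- 4L
    }
    ## treatment entry / relapse, parallel on stage-start states
    s1 <- which(st == 1L)
    s4 <- which(st == 4L)
    tin <- s1[stats::runif(length(s1)) < q_t]
    tout <- s4[stats::runif(length(s4)) < q_r]
    st[tin] <- 4L
    st[tout] <- 1L
    if (ent_rate > 0) {
      ne <- stats::rpois(1, ent_rate)
      if (ne > 0) {
        st <- c(st, rep(1L, ne))
        rg <- c(rg, sample.int(K, ne, replace = TRUE,
                               prob = profile$population_proportion))
        entrantsc <- entrantsc + ne
      }
    }
    alive <- sum(st != 6L)
    if (alive + fatal != init_total + entrantsc)
      stop("internal consistency error: conservation violated at step ", s,
           call. = FALSE)
  }

  structure(list(fatal = fatal,
                 nonfatal = nonfatal,
                 ops_od = ops_odc,
                 averted = avertedc,
                 ops_visits = visits,
                 entrants = entrantsc,
                 mean_ops_occupancy = if (open_steps_seen > 0)
                   occup / open_steps_seen else 0,
                 final_active = sum(st == 1L),
                 final_treatment = sum(st == 4L),
                 revived = revived,
                 seed = seed),
            class = "ops_sim_result")
}
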