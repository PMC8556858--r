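## Common-random-numbers couplings: the paired constructions must leave
## every marginal law unchanged (only the variance of differences drops).

test_that("coupled treatment pair reproduces both arm marginals and the mean-field difference", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_nonfatal_od = 0.4, annual_fatal_od = 0.1,
                      new_entrants_per_day = 1)
  d <- treatment_pair_crn(p, 0.15, 0.60, n_reps = 80, seed = 3)
  expect_identical(nrow(d), 80L)
  mc_se <- function(x) sd(x) / sqrt(length(x))
  ## arm marginals against the exact mean-field expectations
  mf_a <- expected_annual_events_no_ops(p)
  pb <- p; pb$annual_treatment_entry <- 0.60
  mf_b <- expected_annual_events_no_ops(pb, init_treatment_entry = 0.15)
  expect_lt(abs(mean(d$nonfatal_a) - mf_a$nonfatal), 3 * mc_se(d$nonfatal_a))
  expect_lt(abs(mean(d$nonfatal_b) - mf_b$nonfatal), 3 * mc_se(d$nonfatal_b))
  expect_lt(abs(mean(d$fatal_a) - mf_a$fatal), 3 * mc_se(d$fatal_a))
  ## paired difference against the mean-field difference
  expect_lt(abs(mean(d$nonfatal_reduction) -
                  (mf_a$nonfatal - mf_b$nonfatal)),
            3 * mc_se(d$nonfatal_reduction))
  ## pairing shrinks the error of the difference well below the
  ## independent-arms error
  expect_lt(mc_se(d$nonfatal_reduction),
            0.5 * sqrt(mc_se(d$nonfatal_a)^2 + mc_se(d$nonfatal_b)^2))
  ## determinism and input validation
  expect_identical(treatment_pair_crn(p, 0.15, 0.60, n_reps = 5, seed = 9),
                   treatment_pair_crn(p, 0.15, 0.60, n_reps = 5, seed = 9))
  expect_error(treatment_pair_crn(p, 0.6, 0.15, n_reps = 2), "rate_b")
  p2 <- p; p2$ops_capacity <- 10
  expect_error(treatment_pair_crn(p2, 0.15, 0.6, n_reps = 2), "no-OPS")
})

test_that("paired and independent treatment sweeps agree within combined error", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_nonfatal_od = 0.4, annual_fatal_od = 0.1,
                      new_entrants_per_day = 0)
  prof <- tiny_profile()
  crn <- treatment_sweep(p, prof, rates = c(0.15, 0.5), n_replicates = 80,
                         seed = 7, pairing = "crn")
  ind <- treatment_sweep(p, prof, rates = c(0.15, 0.5), n_replicates = 80,
                         seed = 7, pairing = "independent")
  a <- crn$table[2, ]
  b <- ind$table[2, ]
  expect_lt(abs(a$nonfatal_reduction - b$nonfatal_reduction),
            3 * sqrt(a$nonfatal_reduction_se^2 + b$nonfatal_reduction_se^2))
  expect_lt(abs(a$fatal_reduction - b$fatal_reduction),
            3 * sqrt(a$fatal_reduction_se^2 + b$fatal_reduction_se^2))
  ## baseline rows are exactly zero in both
  expect_identical(crn$table$nonfatal_reduction[1], 0)
  expect_identical(ind$table$fatal_reduction[1], 0)
})

test_that("revived tagging yields paired direct effects matching independent runs", {
  p <- ops_parameters(n_users_initial = 2000, horizon_days = 30,
                      annual_fatal_od = 0.2, annual_nonfatal_od = 0.3,
                      new_entrants_per_day = 0)
  prof <- single_ring_profile()
  crn <- direct_effects(p, prof, capacity = 10, n_replicates = 80, seed = 11)
  ind <- direct_effects(p, prof, capacity = 10, n_replicates = 80, seed = 11,
                        pairing = "independent")
  expect_lt(abs(crn$fatal_reduction - ind$fatal_reduction),
            3 * sqrt(crn$fatal_reduction_se^2 + ind$fatal_reduction_se^2))
  expect_lt(abs(crn$nonfatal_increase - ind$nonfatal_increase),
            3 * sqrt(crn$nonfatal_increase_se^2 + ind$nonfatal_increase_se^2))
  ## the paired estimator is sharply variance-reduced
  expect_lt(crn$nonfatal_increase_se, 0.5 * ind$nonfatal_increase_se)
  ## saturation oracle: reduction per station ~ open_steps * p_fatal_use
  pf <- per_use_od_prob(0.2, uses_per_year(p))
  oracle <- 10 * ops_open_steps_per_day(p) * p$horizon_days * pf
  expect_lt(abs(crn$fatal_reduction - oracle),
            max(3 * crn$fatal_reduction_se, 0.1 * oracle))
  expect_error(direct_effects(p, prof, capacity = 0), "capacity")
})

test_that("tagged counters stay zero without an OPS and stay consistent with one", {
  p0 <- fast_params(horizon_days = 10)
  r0 <- run_replicates(p0, tiny_profile(), n_reps = 5, seed = 2)
  expect_true(all(r0$replicates$tagged_fatal == 0))
  expect_true(all(r0$replicates$tagged_nonfatal == 0))
  p1 <- ops_parameters(n_users_initial = 2000, horizon_days = 30,
                       annual_fatal_od = 0.5, annual_nonfatal_od = 0.5,
                       ops_capacity = 10, new_entrants_per_day = 0)
  r1 <- run_replicates(p1, single_ring_profile(), n_reps = 40, seed = 6)
  d <- r1$replicates
  expect_true(all(d$averted <= d$ops_od))
  ## reconstructed coupled-baseline marginals are valid counts
  expect_true(all(d$fatal - d$tagged_fatal + d$averted >= 0))
  expect_true(all(d$nonfatal - d$tagged_nonfatal - d$averted >= 0))
  ## tagged users exist, so some of their events should be recorded
  expect_gt(sum(d$tagged_nonfatal), 0)
})
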