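## Scaled-down scenario experiments: small cohorts with inflated overdose
## rates so differences are detectable with tens of replicates.

test_that("capacity sweep reports zero differences for the no-OPS arm", {
  p <- ops_parameters(n_users_initial = 1500, horizon_days = 15,
                      annual_fatal_od = 0.1, annual_nonfatal_od = 0.3,
                      new_entrants_per_day = 0)
  sw <- capacity_sweep(p, tiny_profile(), capacities = c(0, 5, 20),
                       n_replicates = 20, baseline_replicates = 20, seed = 3)
  t0 <- sw$table[sw$table$capacity == 0, ]
  expect_identical(t0$fatal_reduction, 0)
  expect_identical(t0$nonfatal_change, 0)
  expect_identical(nrow(sw$table), 3L)
  expect_true(all(c("fatal_reduction_se", "nonfatal_change_se") %in%
                    names(sw$table)))
  expect_true(is.finite(sw$slope_per_30))
})

test_that("fatal reduction grows with capacity and tracks the saturation slope", {
  p <- ops_parameters(n_users_initial = 2000, horizon_days = 30,
                      annual_fatal_od = 0.2, annual_nonfatal_od = 0.3,
                      new_entrants_per_day = 0)
  sw <- capacity_sweep(p, single_ring_profile(),
                       capacities = c(0, 10, 20, 40),
                       n_replicates = 50, seed = 7)
  tab <- sw$table
  ## monotone within 2 combined MC standard errors
  r <- tab$fatal_reduction
  se <- tab$fatal_reduction_se
  for (i in seq_len(nrow(tab) - 1)) {
    expect_gt(r[i + 1] - r[i], -2 * sqrt(se[i]^2 + se[i + 1]^2))
  }
  ## saturation oracle per station
  pf <- per_use_od_prob(0.2, uses_per_year(p))
  open_steps <- ops_open_steps_per_day(p) * p$horizon_days
  oracle_slope_30 <- 30 * open_steps * pf
  expect_lt(abs(sw$slope_per_30 - oracle_slope_30),
            max(3 * sw$slope_se_per_30, 0.15 * oracle_slope_30))
})

test_that("paired proportion sweep locates the analytic break-even", {
  p <- ops_parameters(n_users_initial = 2000, horizon_days = 30,
                      annual_fatal_od = 0.2, annual_nonfatal_od = 0.3,
                      new_entrants_per_day = 0)
  sw <- proportion_sweep(p, single_ring_profile(),
                         proportions = seq(0.3, 1, by = 0.1),
                         capacities = c(10, 30), n_replicates = 40, seed = 5)
  expect_true(all(sw$breakeven$bracketed))
  analytic <- breakeven_proportion_analytic(p)
  for (i in seq_len(nrow(sw$breakeven))) {
    expect_lt(abs(sw$breakeven$proportion_at_zero[i] - analytic),
              max(3 * sw$breakeven$se[i], 0.02))
  }
  ## net change at proportion 1 is positive (revived fatalities add
  ## nonfatal overdoses), and the surface is monotone in the proportion
  s10 <- sw$surface[sw$surface$capacity == 10, ]
  expect_gt(s10$mean_change[nrow(s10)], 0)
  expect_true(all(diff(s10$mean_change) >= 0))
})

test_that("unbracketed break-even is reported as such", {
  p <- ops_parameters(n_users_initial = 2000, horizon_days = 10,
                      annual_fatal_od = 0.2, annual_nonfatal_od = 0.3,
                      new_entrants_per_day = 0)
  sw <- proportion_sweep(p, single_ring_profile(),
                         proportions = c(0.95, 1), capacities = 10,
                         n_replicates = 20, seed = 5)
  expect_false(sw$breakeven$bracketed[1])
  expect_true(is.na(sw$breakeven$reduction[1]))
})

test_that("independent and paired proportion estimates agree within error", {
  p <- ops_parameters(n_users_initial = 1500, horizon_days = 20,
                      annual_fatal_od = 0.25, annual_nonfatal_od = 0.35,
                      new_entrants_per_day = 0)
  prof <- single_ring_profile()
  pa <- proportion_sweep(p, prof, proportions = c(0.4, 1), capacities = 20,
                         n_replicates = 60, seed = 9)
  ind <- proportion_sweep(p, prof, proportions = c(0.4, 1), capacities = 20,
                          n_replicates = 60, seed = 9, method = "independent")
  for (pr in c(0.4, 1)) {
    a <- pa$surface[pa$surface$proportion == pr, ]
    b <- ind$surface[ind$surface$proportion == pr, ]
    expect_lt(abs(a$mean_change - b$mean_change),
              3 * sqrt(a$se_change^2 + b$se_change^2))
  }
})

test_that("treatment sweep differences are zero at baseline and grow with the rate", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_nonfatal_od = 0.4, annual_fatal_od = 0.1,
                      new_entrants_per_day = 0)
  sw <- treatment_sweep(p, tiny_profile(), rates = c(0.15, 0.6),
                        n_replicates = 60, seed = 13)
  tab <- sw$table
  expect_identical(tab$fatal_reduction[1], 0)
  expect_identical(tab$nonfatal_reduction[1], 0)
  expect_gt(tab$nonfatal_reduction[2], 0)
  ## analytic relaxation approximation: equilibrium shift x one-year
  ## averaging factor x baseline event rate
  spy <- steps_per_year(p)
  q_r <- annual_to_step_prob(0.5, spy)
  qt <- vapply(c(0.15, 0.6), annual_to_step_prob, numeric(1), spy)
  N <- 3000 + round(equilibrium_treatment_count(3000, 0.15, 0.5))
  horizon_steps <- 30 * steps_per_day(p)
  k <- qt[2] + q_r
  a_inf <- N * q_r / k
  avg_active <- a_inf + (3000 - a_inf) * (1 - exp(-k * horizon_steps)) /
    (k * horizon_steps)
  pnf <- per_use_od_prob(0.4, uses_per_year(p))
  ## baseline arm sits at its equilibrium (mean active ~3000); the raised
  ## arm relaxes toward a_inf, so the averted events are the active-user
  ## deficit times the per-user event intensity over the horizon
  expected_red <- (3000 - avg_active) * (p$uses_per_day * 30) * pnf
  expect_lt(abs(tab$nonfatal_reduction[2] - expected_red),
            max(3 * tab$nonfatal_reduction_se[2], 0.15 * expected_red))
})

test_that("spatial attribution concentrates revivals near the site", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_fatal_od = 0.2, annual_nonfatal_od = 0.3,
                      ops_capacity = 10, new_entrants_per_day = 0)
  prof <- tiny_profile()
  reps <- run_replicates(p, prof, n_reps = 40, seed = 19)
  at <- spatial_attribution(reps, prof)
  expect_gt(sum(at$per_ring$revived), 0)
  expect_equal(sum(at$per_ring$revived_share), 1, tolerance = 1e-12)
  ## revived share within any radius >= population share (visit probability
  ## decays with distance)
  expect_true(all(at$cumulative$revived_share >=
                    at$cumulative$population_share - 1e-9))
  ## single-ring population: all revivals in that ring
  reps1 <- run_replicates(ops_parameters(n_users_initial = 1000,
                                         horizon_days = 10,
                                         annual_fatal_od = 0.3,
                                         ops_capacity = 5,
                                         new_entrants_per_day = 0),
                          single_ring_profile(), n_reps = 10, seed = 20)
  at1 <- spatial_attribution(reps1, single_ring_profile())
  expect_equal(at1$per_ring$revived_share, 1)
})
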