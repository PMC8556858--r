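test_that("initialization allocates exact totals by largest remainder", {
  expect_equal(largest_remainder(10, c(1, 1, 1)), c(4L, 3L, 3L))
  expect_equal(sum(largest_remainder(101, runif(7))), 101)
  prof <- default_ring_profile(seed = 1, n = 5000)
  st <- initialize_state(ops_parameters(), prof)
  expect_identical(sum(st$not_using), 55000L)
  expect_identical(sum(st$treatment),
                   as.integer(round(equilibrium_treatment_count(55000, 0.15, 0.5))))
  ## single-ring profile puts all mass in that ring
  st1 <- initialize_state(fast_params(), single_ring_profile())
  expect_identical(st1$not_using, 2000L)
})

test_that("population is conserved when nothing can kill or add users", {
  p <- fast_params(annual_nonfatal_od = 0, annual_fatal_od = 0)
  r <- simulate_year(p, tiny_profile(), seed = 5)
  expect_identical(r$fatal, 0)
  expect_identical(r$nonfatal, 0)
  expect_equal(r$final_active + r$final_treatment,
               2000 + round(equilibrium_treatment_count(2000, 0.15, 0.5)))
})

test_that("no OPS means no OPS visits; same seed means identical results", {
  p <- fast_params(ops_capacity = 0)
  r <- simulate_year(p, tiny_profile(), seed = 9)
  expect_identical(r$ops_visits, 0)
  expect_identical(r$ops_od, 0)
  expect_identical(r$mean_ops_occupancy, 0)
  expect_identical(simulate_year(p, tiny_profile(), seed = 9), r)
  reps <- run_replicates(p, tiny_profile(), n_reps = 4, seed = 2)
  expect_identical(run_replicates(p, tiny_profile(), n_reps = 4, seed = 2),
                   reps)
})

test_that("no fatal overdose can originate in the OPS", {
  ## everyone attempts the site, capacity is unconstrained, fatal risk is
  ## extreme: without the in-OPS guarantee this would kill most of the cohort
  p <- ops_parameters(n_users_initial = 300, horizon_days = 5,
                      annual_fatal_od = 0.999, annual_nonfatal_od = 0,
                      ops_capacity = 10000, ops_hours_per_day = 24,
                      new_entrants_per_day = 0)
  r <- simulate_year(p, single_ring_profile(), seed = 13)
  expect_identical(r$fatal, 0)
  expect_gt(r$ops_visits, 0)
  expect_gt(r$ops_od, 0)
  expect_true(r$averted <= r$ops_od)
})

test_that("OPS occupancy saturates at capacity when demand far exceeds it", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 10,
                      ops_capacity = 5, new_entrants_per_day = 0)
  r <- simulate_year(p, single_ring_profile(), seed = 17)
  ## demand per open step ~ 3000/12 >> 5, so every open step is full
  expect_equal(r$mean_ops_occupancy, 5)
  expect_equal(r$ops_visits,
               5 * ops_open_steps_per_day(p) * p$horizon_days)
})

test_that("saturated-site averted fatalities match the closed-form oracle", {
  ## averted / year ~= capacity * open_steps * p_fatal_use under saturation
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_fatal_od = 0.10, annual_nonfatal_od = 0.30,
                      ops_capacity = 5, new_entrants_per_day = 0)
  reps <- run_replicates(p, single_ring_profile(), n_reps = 60, seed = 23)
  pf <- per_use_od_prob(0.10, uses_per_year(p))
  open_steps <- ops_open_steps_per_day(p) * p$horizon_days
  oracle <- 5 * open_steps * pf
  expect_lt(abs(replicate_stat(reps, "averted") - oracle),
            3 * replicate_stat(reps, "averted", "se"))
})

test_that("a lone user with certain use and certain fatality dies at the first step", {
  p <- ops_parameters(n_users_initial = 1, uses_per_day = 48,
                      annual_fatal_od = 1, annual_nonfatal_od = 0,
                      annual_treatment_entry = 0, horizon_days = 1,
                      new_entrants_per_day = 0)
  r <- simulate_year(p, single_ring_profile(), seed = 3)
  expect_identical(r$fatal, 1)
  expect_identical(r$final_active + r$final_treatment, 0)
  m <- simulate_year_microsim(p, single_ring_profile(), seed = 3, n_agents = 1)
  expect_identical(m$fatal, 1)
})

test_that("baseline annual fatal count stays near the mean-field expectation", {
  p <- ops_parameters()
  ev <- expected_annual_events_no_ops(p)
  r <- simulate_year(p, default_ring_profile(seed = 1), seed = 31)
  ## inter-replicate SD is ~sqrt(mean); 5 SDs is a generous single-draw band
  expect_lt(abs(r$fatal - ev$fatal), 5 * sqrt(ev$fatal))
})

test_that("microsim and compartmental engines agree in distribution", {
  p <- stress_params(ops_capacity = 10, n_replicates = 1)
  prof <- tiny_profile()
  n_reps <- 120
  comp <- run_replicates(p, prof, n_reps = n_reps, seed = 41)
  micro <- t(vapply(seq_len(n_reps), function(i) {
    m <- simulate_year_microsim(p, prof, seed = 1000 + i, n_agents = 500)
    c(fatal = m$fatal, nonfatal = m$nonfatal, ops_od = m$ops_od)
  }, numeric(3)))
  for (metric in c("fatal", "nonfatal", "ops_od")) {
    se_m <- sd(micro[, metric]) / sqrt(n_reps)
    se_c <- replicate_stat(comp, metric, "se")
    expect_lt(abs(mean(micro[, metric]) - replicate_stat(comp, metric)),
              3 * sqrt(se_m^2 + se_c^2))
  }
})

test_that("microsim respects zero rates and determinism", {
  p <- fast_params(annual_nonfatal_od = 0, annual_fatal_od = 0, horizon_days = 3)
  m <- simulate_year_microsim(p, tiny_profile(), seed = 7, n_agents = 200)
  expect_identical(m$fatal + m$nonfatal, 0)
  expect_identical(simulate_year_microsim(p, tiny_profile(), seed = 7,
                                          n_agents = 200), m)
})

test_that("replicate summaries expose means and Monte-Carlo standard errors", {
  p <- fast_params(horizon_days = 5)
  reps <- run_replicates(p, tiny_profile(), n_reps = 8, seed = 11)
  expect_identical(nrow(reps$replicates), 8L)
  expect_equal(replicate_stat(reps, "nonfatal"), mean(reps$replicates$nonfatal))
  expect_equal(replicate_stat(reps, "nonfatal", "se"),
               sd(reps$replicates$nonfatal) / sqrt(8))
  expect_error(replicate_stat(reps, "bogus"), "unknown metric")
  ## n_reps = 1: summary equals the single replicate
  one <- run_replicates(p, tiny_profile(), n_reps = 1, seed = 11)
  expect_equal(replicate_stat(one, "fatal"), one$replicates$fatal[1])
  ## serialisation
  paths <- write_replicates(reps,
                            csv_path = withr::local_tempfile(fileext = ".csv"),
                            json_path = withr::local_tempfile(fileext = ".json"))
  expect_true(file.exists(paths$csv) && file.exists(paths$json))
  js <- jsonlite::read_json(paths$json)
  expect_equal(js$mean_nonfatal, replicate_stat(reps, "nonfatal"))
})

test_that("two master seeds give statistically compatible replicate means", {
  p <- ops_parameters(n_users_initial = 3000, horizon_days = 30,
                      annual_nonfatal_od = 0.3, new_entrants_per_day = 0)
  a <- run_replicates(p, tiny_profile(), n_reps = 80, seed = 1)
  b <- run_replicates(p, tiny_profile(), n_reps = 80, seed = 99)
  se <- sqrt(replicate_stat(a, "nonfatal", "se")^2 +
               replicate_stat(b, "nonfatal", "se")^2)
  expect_lt(abs(replicate_stat(a, "nonfatal") - replicate_stat(b, "nonfatal")),
            4 * se)
})
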