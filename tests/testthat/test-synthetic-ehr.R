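test_that("simulation is deterministic and per-woman substreams are stable", {
  p <- simulation_params(n_women = 300, seed = 1L)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$women, b$women)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$ground_truth$episodes, b$ground_truth$episodes)

  # enlarging the cohort appends women without touching existing ones
  big <- simulate_cohort(simulation_params(n_women = 400, seed = 1L))
  expect_identical(a$women, big$women[seq_len(nrow(a$women)), ])
  expect_identical(a$episodes, big$episodes[seq_len(nrow(a$episodes)), ])
})

test_that("zero baseline exposure and zero initiation emit no index prescriptions", {
  p <- simulation_params(
    n_women = 400, seed = 5L,
    baseline_exposure_prob = 0,
    interval_initiation_probs = c(
      PRE90 = 0, T1 = 0, T2 = 0, T3 = 0, POST90 = 0, POST180 = 0
    )
  )
  sim <- simulate_cohort(p)
  expect_false(any(sim$prescriptions$atc_code == "N03AG01"))
  expect_false(any(sim$ground_truth$episodes$exposed_episode))
})

test_that("parameter validation rejects bad probabilities and date ordering", {
  expect_error(simulation_params(baseline_exposure_prob = 1.2), "probability")
  expect_error(simulation_params(monthly_conception_prob = -0.1), "probability")
  expect_error(
    simulation_params(intervention_date = as.Date("2021-01-01")),
    "observation_start < intervention_date < observation_end"
  )
})

test_that("tables are relationally consistent and no record predates birth", {
  sim <- default_sim()
  expect_true(all(sim$episodes$woman_id %in% sim$women$woman_id))
  expect_true(all(sim$prescriptions$woman_id %in% sim$women$woman_id))
  expect_true(all(sim$diagnoses$woman_id %in% sim$women$woman_id))
  birth <- sim$women$birth_date
  names(birth) <- sim$women$woman_id
  expect_true(all(
    sim$prescriptions$start_date > birth[as.character(sim$prescriptions$woman_id)]
  ))
  expect_true(all(
    sim$diagnoses$onset_date > birth[as.character(sim$diagnoses$woman_id)]
  ))
  expect_true(all(sim$episodes$lmp_date >= simulation_params()$observation_start))
  expect_true(all(sim$episodes$lmp_date < sim$episodes$end_date))
})

test_that("exposed-episode fraction matches the binomial target", {
  sim <- default_sim()
  gt <- sim$ground_truth$episodes
  n <- nrow(gt)
  # recount from the emitted tables, not from the latent draws
  flag <- episode_exposed(sim$prescriptions, sim$episodes, "N03AG01")
  frac <- mean(flag)
  p0 <- 0.003
  # the calendar trend moves the per-episode probability around p0; allow
  # 3 binomial SDs around the baseline target
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n) + 1e-12)
})

test_that("gestation mixture is bimodal: early terminations and term deliveries", {
  sim <- default_sim()
  w <- sim$episodes$gestational_weeks
  expect_true(all(w <= 45))
  expect_gt(mean(w < 15), 0.15) # early-termination mass
  expect_gt(mean(w >= 37), 0.55) # term mass
  expect_true(all(sim$episodes$outcome_code[w < 15] == "abortion"))
})

test_that("per-trimester exposure prevalence decreases T1 to T3", {
  # structural property of the continuation chain, checked where flags are
  # plentiful enough to measure
  sim <- dense_sim()
  gt <- sim$ground_truth$episodes
  long <- truth_long(gt, "prev")
  prev <- tapply(long$flag, long$label, mean)
  expect_gt(prev[["T1"]], prev[["T2"]])
  expect_gt(prev[["T2"]], prev[["T3"]])
})

test_that("monthly series generator follows its closed-form Poisson model", {
  p <- simulation_params(
    observation_start = as.Date("2012-01-01"),
    intervention_date = as.Date("2014-10-01"),
    seed = 9L
  )
  s <- simulate_monthly_series(p, 96)
  truth <- attr(s, "truth")
  expect_equal(nrow(s), 96)
  expect_true(all(s$numerator >= 0))

  # with no intervention effect the expected rate continues the pre trend
  p0 <- simulation_params(
    observation_start = as.Date("2012-01-01"),
    intervention_date = as.Date("2014-10-01"),
    level_change = 0, slope_change = 0, seed = 9L
  )
  s0 <- simulate_monthly_series(p0, 96)
  mu0 <- attr(s0, "truth")$expected
  t <- 0:95
  expect_equal(mu0, 1000 * 0.003 * exp(p0$pre_slope * t), tolerance = 1e-12)

  # consecutive post-intervention expected ratios equal exp(pre_slope + slope_change)
  mu <- truth$expected
  k <- truth$intervention_index
  post_ratio <- mu[(k + 3):96] / mu[(k + 2):95]
  expect_equal(post_ratio, rep(exp(p$pre_slope + p$slope_change), length(post_ratio)),
    tolerance = 1e-12
  )

  # mean pre-period count ~ denominator * baseline over replicates
  means <- vapply(1:200, function(i) {
    pi <- simulation_params(
      observation_start = as.Date("2012-01-01"),
      intervention_date = as.Date("2014-10-01"),
      pre_slope = 0, seed = 5000L + i
    )
    si <- simulate_monthly_series(pi, 96)
    mean(si$numerator[1:33])
  }, numeric(1))
  expect_equal(mean(means), 3, tolerance = 0.05)

  expect_error(
    simulate_monthly_series(p, 24),
    "strictly inside"
  )
})
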