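test_that("range overlap uses the at-least-one-shared-day rule", {
  expect_true(ranges_overlap(
    as.Date("2015-01-01"), as.Date("2015-03-01"),
    as.Date("2015-03-01"), as.Date("2015-06-01")
  ))
  expect_false(ranges_overlap(
    as.Date("2015-01-01"), as.Date("2015-02-28"),
    as.Date("2015-03-01"), as.Date("2015-06-01")
  ))

  set.seed(11)
  base <- as.Date("2014-01-01")
  for (i in 1:1000) {
    s1 <- base + sample.int(400, 1)
    e1 <- s1 + sample.int(120, 1) - 1
    s2 <- base + sample.int(400, 1)
    e2 <- s2 + sample.int(120, 1) - 1
    expect_identical(
      ranges_overlap(s1, e1, s2, e2),
      day_overlap_oracle(s1, e1, s2, e2)
    )
  }
})

test_that("prevalent classification matches any-overlap of the ATC prefix", {
  interval <- list(start_date = as.Date("2015-03-01"), end_date = as.Date("2015-06-01"))
  expect_false(classify_prevalent(make_rx(integer(0), character(0), character(0)), interval, "N03AG01"))
  rx2 <- make_rx(1L, c("2015-02-01", "2015-04-01"), c("2015-03-10", "2015-05-01"))
  expect_true(classify_prevalent(rx2, interval, "N03AG01"))
  # prefix matching: subgroup-level prefix matches the full substance code
  expect_true(classify_prevalent(rx2, interval, "N03AG"))
  expect_false(classify_prevalent(rx2, interval, "N03AX"))
})

test_that("incident classification enforces the washout definition", {
  obs <- as.Date("2011-01-01")
  t2 <- list(start_date = as.Date("2015-04-09"), end_date = as.Date("2015-07-15"))
  # initiation mid-window, nothing in the prior year: incident
  rx <- make_rx(1L, "2015-05-20", "2015-08-17")
  out <- classify_incident(rx, t2, "N03AG01", 365L, obs)
  expect_true(out$washout_eligible)
  expect_true(out$incident)

  # continuously active from 2 years before: prevalent wherever overlapped,
  # incident nowhere
  rx_long <- make_rx(1L, "2013-04-01", "2016-01-01")
  expect_true(classify_prevalent(rx_long, t2, "N03AG01"))
  out <- classify_incident(rx_long, t2, "N03AG01", 365L, obs)
  expect_false(out$washout_eligible)
  expect_false(out$incident)

  # washout window not verifiable in the data: ineligible even if clean
  early <- list(start_date = as.Date("2011-06-01"), end_date = as.Date("2011-09-01"))
  out <- classify_incident(rx[0, ], early, "N03AG01", 365L, obs)
  expect_false(out$washout_eligible)
})

test_that("episode exposure needs overlap with gestation itself", {
  eps <- make_episodes("2015-01-01", "2015-10-08")
  # exposure confined to the pre-conception window does not expose the episode
  expect_false(episode_exposed(make_rx(1L, "2014-10-15", "2014-12-31"), eps, "N03AG01"))
  # a single shared day, the final day of gestation, does
  expect_true(episode_exposed(make_rx(1L, "2015-10-08", "2015-12-01"), eps, "N03AG01"))
})

test_that("incident implies prevalent and washout-eligible on random inputs", {
  set.seed(21)
  obs <- as.Date("2011-01-01")
  for (rep in 1:25) {
    lmp <- as.Date("2012-01-01") + sample.int(2500, 8)
    eps <- make_episodes(lmp, lmp + sample(c(60:100, 200:290), 8, replace = TRUE),
      woman_id = sample.int(4, 8, replace = TRUE)
    )
    n_rx <- sample.int(12, 1)
    starts <- as.Date("2011-06-01") + sample.int(3000, n_rx)
    rx <- make_rx(sample.int(4, n_rx, replace = TRUE), starts,
      starts + sample.int(200, n_rx)
    )
    iv <- build_intervals(eps)
    st <- classify_exposure(iv, eps, rx, "N03AG01", 365L, obs)
    expect_true(all(st$prevalent[st$incident]))
    expect_true(all(st$washout_eligible[st$incident]))
  }
})

test_that("lengthening the washout never increases the incident count", {
  set.seed(22)
  obs <- as.Date("2011-01-01")
  lmp <- as.Date("2013-01-01") + sample.int(2000, 30)
  eps <- make_episodes(lmp, lmp + sample(200:290, 30, replace = TRUE),
    woman_id = sample.int(12, 30, replace = TRUE)
  )
  starts <- as.Date("2012-01-01") + sample.int(2800, 60)
  rx <- make_rx(sample.int(12, 60, replace = TRUE), starts, starts + sample.int(150, 60))
  iv <- build_intervals(eps)
  counts <- vapply(c(90L, 180L, 365L, 540L, 730L), function(w) {
    sum(classify_exposure(iv, eps, rx, "N03AG01", w, obs)$incident)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classification is invariant to prescription row order", {
  set.seed(23)
  lmp <- as.Date("2013-06-01") + sample.int(1500, 10)
  eps <- make_episodes(lmp, lmp + 280, woman_id = sample.int(5, 10, replace = TRUE))
  starts <- as.Date("2012-06-01") + sample.int(2500, 40)
  rx <- make_rx(sample.int(5, 40, replace = TRUE), starts, starts + 100)
  iv <- build_intervals(eps)
  obs <- as.Date("2011-01-01")
  a <- classify_exposure(iv, eps, rx, "N03AG01", 365L, obs)
  b <- classify_exposure(iv, eps, rx[sample.int(40), ], "N03AG01", 365L, obs)
  expect_equal(a, b)
})

test_that("classification recovers the generator's ground truth exactly", {
  for (sim in list(dense_sim(), default_sim())) {
    gt <- sim$ground_truth$episodes
    obs <- sim$ground_truth$params$observation_start
    iv <- build_intervals(sim$episodes)
    st <- classify_exposure(
      iv, sim$episodes, sim$prescriptions, "N03AG01",
      sim$ground_truth$params$washout_days, obs
    )
    st$label <- as.character(st$label)
    for (fam in c("prev", "elig", "inc")) {
      truth <- truth_long(gt, fam)
      merged <- merge(st, truth, by = c("episode_id", "label"))
      expect_equal(nrow(merged), nrow(st))
      got <- switch(fam,
        prev = merged$prevalent,
        elig = merged$washout_eligible,
        inc = merged$incident
      )
      expect_identical(got, as.logical(merged$flag))
    }
    # episode-level flag and total exposed count
    flag <- episode_exposed(sim$prescriptions, sim$episodes, "N03AG01")
    expect_identical(flag, gt$exposed_episode)
    expect_equal(sum(flag), sum(gt$exposed_episode))
  }
})
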