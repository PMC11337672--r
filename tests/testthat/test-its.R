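series_params <- function(seed, ...) {
  simulation_params(
    observation_start = as.Date("2012-01-01"),
    intervention_date = as.Date("2014-10-01"),
    seed = seed, ...
  )
}

test_that("design matrix encodes step and slope-change terms correctly", {
  s <- simulate_monthly_series(series_params(3L), 96)
  d <- build_its_design(s, as.Date("2014-10-01"))
  # Jan 2012 .. Oct 2014 are pre months; the first post month is Nov 2014
  expect_equal(sum(d$post == 0), 34)
  expect_equal(sum(d$post == 1), 62)
  expect_equal(d$post[d$month == as.Date("2014-10-01")], 0)
  expect_equal(d$post[d$month == as.Date("2014-11-01")], 1)
  expect_equal(d$t_post[d$month == as.Date("2014-11-01")], 1)
  # final month: months elapsed since the intervention month
  expect_equal(d$t_post[nrow(d)], 62)
  expect_true(all(d$t_post[d$post == 0] == 0))
  expect_equal(
    names(d), c("month", "t", "y", "offset", "rate", "post", "t_post")
  )

  d1 <- build_its_design(s, as.Date("2014-10-01"), n_lags = 1)
  expect_equal(nrow(d1), 95)
  expect_true("lag_rate" %in% names(d1))

  expect_error(build_its_design(s, as.Date("2030-01-01")), "strictly inside")
  expect_error(build_its_design(s, as.Date("2011-01-01")), "strictly inside")
  expect_error(build_its_design(s, as.Date("2014-10-01"), n_lags = 2), "0 or 1")
})

test_that("slope-change recovery and null coverage behave over replicates", {
  est <- numeric(60)
  for (i in seq_along(est)) {
    s <- simulate_monthly_series(series_params(7000L + i), 96)
    f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
    est[i] <- f$monthly_pct_change$estimate
  }
  expect_lt(abs(mean(est) - 100 * (exp(log(0.973)) - 1)), 0.5)

  cover <- logical(60)
  for (i in seq_along(cover)) {
    s <- simulate_monthly_series(
      series_params(8000L + i, level_change = 0, slope_change = 0), 96
    )
    f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
    cover[i] <- f$monthly_pct_change$ci_low <= 0 && 0 <= f$monthly_pct_change$ci_high
  }
  expect_gte(mean(cover), 0.9)
})

test_that("Poisson AIC beats the Gaussian comparator on Poisson counts", {
  wins <- vapply(1:20, function(i) {
    s <- simulate_monthly_series(series_params(9000L + i), 96)
    d <- build_its_design(s, as.Date("2014-10-01"))
    fit_its(d, "poisson")$aic < fit_its(d, "gaussian")$aic
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("fit guards reject degenerate or too-short inputs", {
  s <- simulate_monthly_series(series_params(3L), 96)
  d <- build_its_design(s, as.Date("2014-10-01"))
  d0 <- d
  d0$y <- 0L
  expect_error(fit_its(d0), "all monthly counts are zero")
  expect_error(fit_its(d[1:20, ]), "at least 24 months")
})

test_that("doubling denominators shifts only the intercept, by -log 2", {
  s <- simulate_monthly_series(series_params(17L), 96)
  d <- build_its_design(s, as.Date("2014-10-01"))
  f1 <- fit_its(d)
  s2 <- s
  s2$denominator <- 2L * s2$denominator
  f2 <- fit_its(build_its_design(s2, as.Date("2014-10-01")))
  expect_equal(
    f2$coefficients[["(Intercept)"]],
    f1$coefficients[["(Intercept)"]] - log(2),
    tolerance = 1e-6
  )
  expect_equal(
    f2$coefficients[c("t", "post", "t_post")],
    f1$coefficients[c("t", "post", "t_post")],
    tolerance = 1e-6
  )
})

test_that("shifting the time origin never changes the monthly percent change", {
  s <- simulate_monthly_series(series_params(19L), 96)
  f1 <- fit_its(build_its_design(s, as.Date("2014-10-01")))
  s2 <- s
  s2$month <- seq(as.Date("2005-03-01"), by = "month", length.out = nrow(s2))
  f2 <- fit_its(build_its_design(s2, as.Date("2007-12-15")))
  expect_equal(
    f2$monthly_pct_change$estimate, f1$monthly_pct_change$estimate,
    tolerance = 1e-8
  )
  expect_equal(f2$coefficients[["t_post"]], f1$coefficients[["t_post"]], tolerance = 1e-8)
})

test_that("counterfactual contrast has the advertised closed forms", {
  s <- simulate_monthly_series(series_params(23L), 96)
  d <- build_its_design(s, as.Date("2014-10-01"))
  f <- fit_its(d)

  # no intervention terms: contrast is identically zero
  f0 <- f
  f0$coefficients[c("post", "t_post")] <- 0
  out <- counterfactual_contrast(f0, n_boot = 50, seed = 1)
  expect_equal(out$pct_change, 0)

  # pure level drop exp(b2) = 0.9: contrast is exactly -10%
  f9 <- f
  f9$coefficients[["post"]] <- log(0.9)
  f9$coefficients[["t_post"]] <- 0
  out <- counterfactual_contrast(f9, n_boot = 50, seed = 1)
  expect_equal(out$pct_change, -10)

  # bootstrap CI brackets the point estimate at realistic settings
  out <- counterfactual_contrast(f, n_boot = 400, seed = 2)
  expect_lt(out$ci[1], out$pct_change)
  expect_gt(out$ci[2], out$pct_change)

  d_pre <- d[d$post == 0, ]
  class(d_pre) <- class(d)
  expect_error(counterfactual_contrast(f, d_pre), "post-intervention period is empty")
})

test_that("counterfactual CI covers the generator's true contrast", {
  # truth: percent difference of expected post-period totals with and
  # without the intervention terms
  p <- series_params(1L)
  truth_mu <- attr(simulate_monthly_series(p, 96), "truth")
  k <- truth_mu$intervention_index
  t <- 0:95
  post <- t > k
  mu_fact <- truth_mu$expected[post]
  mu_cf <- 1000 * 0.003 * exp(p$pre_slope * t[post])
  true_contrast <- 100 * (sum(mu_fact) - sum(mu_cf)) / sum(mu_cf)
  hit <- vapply(1:40, function(i) {
    s <- simulate_monthly_series(series_params(11000L + i), 96)
    f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
    ci <- counterfactual_contrast(f, n_boot = 300, seed = i)$ci
    ci[1] <= true_contrast && true_contrast <= ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("autocorrelation diagnostic is calibrated and detects AR(1) residuals", {
  # white-noise world: rejection rate close to the nominal level
  pvals <- vapply(1:150, function(i) {
    s <- simulate_monthly_series(series_params(12000L + i), 96)
    f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
    autocorrelation_check(f, max_lag = 6)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 0 & pvals <= 1))
  expect_lt(mean(pvals < 0.05), 0.15)

  # AR(1)-contaminated counts: the refit flag fires in most replicates
  flagged <- vapply(1:20, function(i) {
    set.seed(13000L + i)
    p <- series_params(13000L + i, baseline_exposure_prob = 0.05)
    mu <- attr(simulate_monthly_series(p, 96), "truth")$expected
    e <- as.numeric(stats::arima.sim(list(ar = 0.8), 96, sd = 0.4))
    y <- rpois(96, mu * exp(e))
    s <- tibble::tibble(
      month = seq(as.Date("2012-01-01"), by = "month", length.out = 96),
      numerator = y, denominator = 1000,
      rate_per_1000 = y
    )
    f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
    autocorrelation_check(f, max_lag = 6)$refit_with_lag
  }, logical(1))
  expect_gte(mean(flagged), 0.6)

  s <- simulate_monthly_series(series_params(3L), 96)
  f <- fit_its(build_its_design(s, as.Date("2014-10-01")))
  one <- autocorrelation_check(f, max_lag = 1)
  expect_true(one$p_value >= 0 && one$p_value <= 1)
  expect_error(autocorrelation_check(f, max_lag = 96), "shorter")
})

test_that("lagged-outcome design fits and reports an effect", {
  s <- simulate_monthly_series(series_params(29L), 96)
  d <- build_its_design(s, as.Date("2014-10-01"), n_lags = 1)
  f <- fit_its(d)
  expect_true(is.finite(f$aic))
  expect_true("lag_rate" %in% names(f$coefficients))
  expect_true(is.finite(f$monthly_pct_change$estimate))
})
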