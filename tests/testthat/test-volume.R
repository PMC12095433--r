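weekly_series <- function(n_weeks = 30, pattern = c(40, 42, 44, 41, 38, 20, 15)) {
  daily_series(rep(pattern, n_weeks))
}

test_that("daily counts aggregate encounters and conserve the case total", {
  cal <- generate_calendar(10, 0)
  empty <- build_daily_counts(data.frame(day_index = integer()), cal)
  expect_equal(empty$value, rep(0, 10))

  enc <- data.frame(day_index = c(5L, 5L, 5L, 2L))
  s <- build_daily_counts(enc, cal)
  expect_equal(s$value[s$day_index == 5], 3)
  expect_equal(sum(s$value), nrow(enc))

  expect_error(build_daily_counts(data.frame(day_index = 10L), cal),
               "outside the calendar")
})

test_that("ACF matches the direct-formula oracle and flags weekly structure", {
  set.seed(5)
  x <- rnorm(30)
  cg <- correlogram(x, max_lag = 8)
  # brute-force definition sum((x_t - xbar)(x_{t+k} - xbar)) / sum((x_t - xbar)^2)
  xc <- x - mean(x)
  brute <- sapply(0:8, function(k) {
    sum(xc[1:(30 - k)] * xc[(1 + k):30]) / sum(xc^2)
  })
  expect_equal(cg$acf$acf, brute, tolerance = 1e-10)
  expect_equal(cg$acf$acf[1], 1)
  expect_equal(cg$band, 1.96 / sqrt(30))

  # deterministic weekly series: ACF local maxima at lags 7, 14, 21
  wk <- correlogram(weekly_series(), max_lag = 24)
  a <- wk$acf$acf
  for (lag in c(7, 14, 21)) {
    expect_gt(a[lag + 1], a[lag])
    expect_gt(a[lag + 1], a[lag + 2])
    expect_true(wk$acf$significant[wk$acf$lag == lag])
  }

  # constant series is flagged degenerate
  cg0 <- correlogram(rep(3, 20), max_lag = 5)
  expect_true(cg0$degenerate)
  expect_error(correlogram(x, max_lag = 30), "below the series length")
})

test_that("white-noise false-positive rate stays near the nominal level", {
  set.seed(99)
  rates <- replicate(40, {
    cg <- correlogram(rnorm(365), max_lag = 30)
    mean(cg$acf$significant[-1])
  })
  # nominal 5% two-sided band; allow binomial slack around it
  expect_lt(mean(rates), 0.09)
})

test_that("seasonal differencing has its closed-form limits", {
  wk <- weekly_series()
  d <- seasonal_difference(wk, 7, 1)
  expect_true(all(d$value == 0))
  expect_equal(nrow(d), nrow(wk) - 7L)
  expect_equal(d$day_index[1], 7L)

  lin <- daily_series(3 * (0:49))
  expect_true(all(seasonal_difference(lin, 7, 1)$value == 21))

  # one holiday trough produces exactly two nonzero spikes, 7 days apart
  pat <- rep(c(40, 40, 40, 40, 40, 20, 15), 10)
  pat[24] <- 5
  dd <- seasonal_difference(daily_series(pat), 7, 1)
  nz <- dd$day_index[dd$value != 0]
  expect_equal(nz, c(23L, 30L))
  expect_equal(dd$value[dd$day_index == 23], 5 - 40)
  expect_equal(dd$value[dd$day_index == 30], 40 - 5)

  expect_error(seasonal_difference(daily_series(1:5), 7, 1), "too short")
})

test_that("seasonal random walk fits an exactly periodic series perfectly", {
  wk <- weekly_series(20)
  fit <- fit_sarimax(wk, sarimax_spec(0, 0, 0, 0, 1, 1, 7))
  # zero-variance seasonal difference: exact in-sample one-step errors
  expect_lt(max(abs(fit$residuals)), 1e-6)
  fc <- forecast_sarimax(fit, 7)
  expect_equal(fc, wk$value[1:7], tolerance = 1e-6)
  # the residual correlogram of an exact fit is flagged degenerate
  expect_true(residual_correlogram(fit, 10)$degenerate)

  expect_error(forecast_sarimax(fit, 0), "must be an integer")
  expect_error(fit_sarimax(wk, sarimax_spec(0, 0, 0, 0, 1, 1, 7,
                                            exog_names = "holidays")),
               "xreg is NULL")
})

test_that("seasonal MA coefficient is identifiable from simulated data", {
  est <- sapply(1:5, function(i) {
    x <- simulate_seasonal_ma(730, -0.5, seed = 100 + i)
    unname(stats::coef(fit_sarimax(x, sarimax_spec(0, 0, 0, 0, 1, 1, 7))$fit)["sma1"])
  })
  expect_true(all(abs(est + 0.5) < 0.15))
})

test_that("the holiday volume coefficient is recovered from generator output", {
  cfg1 <- test_gen_config(1)
  true_effect <- cfg1$holiday_volume_mean - cfg1$weekday_volume_mean
  est <- sapply(1:10, function(s) {
    d <- cached(sprintf("vol_runs_%d", s), {
      sim <- generate_encounters(test_gen_config(s))
      list(counts = build_daily_counts(sim$encounters, sim$calendar),
           holidays = as.numeric(sim$calendar$is_holiday))
    })
    fit <- fit_sarimax(d$counts,
                       sarimax_spec(0, 0, 0, 0, 1, 1, 7,
                                    exog_names = "holidays"),
                       xreg = matrix(d$holidays, ncol = 1))
    unname(stats::coef(fit$fit)["holidays"])
  })
  expect_lt(abs(mean(est) - true_effect) / abs(true_effect), 0.2)
})

test_that("rolling one-week-ahead evaluation scores out-of-sample forecasts", {
  wk <- weekly_series(30)  # 210 days
  roll <- rolling_forecast(wk, sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                           origin_start = 139L, step = 7L, horizon = 7L)
  expect_equal(roll$rmse, 0, tolerance = 1e-6)
  expect_equal(nrow(roll$failures), 0L)
  # RMSE equals the brute-force definition over collected pairs
  expect_equal(roll$rmse,
               sqrt(mean((roll$forecasts$forecast - roll$forecasts$actual)^2)))
  # origins advance by `step`, forecasts cover origin+1 .. origin+horizon
  expect_equal(unique(diff(unique(roll$forecasts$origin))), 7)
  expect_true(all(roll$forecasts$target_day > roll$forecasts$origin))

  expect_error(rolling_forecast(wk, sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                                origin_start = 209L), "no valid origins")
})

test_that("noisy weekly data yields nonzero but finite rolling error", {
  set.seed(8)
  y <- rep(c(40, 42, 44, 41, 38, 20, 15), 30) + rnorm(210, 0, 3)
  s <- daily_series(y)
  roll <- rolling_forecast(s, sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                           origin_start = 139L)
  expect_true(is.finite(roll$rmse))
  expect_gt(roll$rmse, 0)
  # parameters reused without refitting still produce forecasts
  roll2 <- rolling_forecast(s, sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                            origin_start = 139L, refit = FALSE)
  expect_true(is.finite(roll2$rmse))
})
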