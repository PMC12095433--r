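test_that("census convention places beds on surgery night through discharge", {
  expect_equal(build_census(3L, 2, 10), c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(build_census(c(0L, 5L), c(0, 0), 8), rep(0, 8))
  # truncation at the calendar edge conserves only in-calendar nights
  expect_equal(build_census(8L, 5, 10), c(rep(0, 8), 1, 1))
  # fractional stays round half-up by default
  expect_equal(build_census(2L, 1.5, 5), c(0, 0, 1, 1, 0))
  expect_equal(build_census(2L, 0.4, 5), rep(0, 5))
  # without rounding the fractional part occupies the final night partially
  expect_equal(build_census(1L, 1.25, 4, round = FALSE), c(0, 1, 0.25, 0))
  expect_error(build_census(1L, -1, 4), "nonnegative")
  expect_error(build_census(4L, 1, 4), "outside")
})

test_that("vectorized census equals the double-loop oracle", {
  set.seed(31)
  for (i in 1:30) {
    n_days <- sample(20:60, 1)
    n_cases <- sample(10:400, 1)
    d <- sample(0:(n_days - 1), n_cases, replace = TRUE)
    l <- rpois(n_cases, 2) + sample(c(0, 0.5), n_cases, replace = TRUE)
    expect_equal(build_census(d, l, n_days), census_oracle(d, l, n_days))
  }
})

test_that("census conservation identity holds exactly for every variant", {
  sim <- generate_encounters(tiny_gen_config(12))
  enc <- sim$encounters
  cal <- sim$calendar
  n_days <- nrow(cal)
  set.seed(1)
  pl <- pmax(0, enc$los_days + rnorm(nrow(enc), 0, 0.8))
  h <- compute_historic_mean_los(enc)
  for (v in c("observed", "predicted", "adjusted", "perfect", "surgery_mean")) {
    cen <- census_variant(enc, cal, v, predicted_los = pl, historic = h)
    los_src <- switch(v,
      observed = , perfect = enc$los_days,
      predicted = pl,
      adjusted = ifelse(enc$planned_same_day_discharge, 0, pl),
      surgery_mean = predict_mean_los_baseline(h, enc$surgery_type))
    nights <- pmin(floor(los_src + 0.5), n_days - enc$day_index)
    expect_identical(sum(cen$value), sum(nights))
  }
  # perfect variant is the observed variant
  expect_identical(census_variant(enc, cal, "perfect")$value,
                   census_variant(enc, cal, "observed")$value)
})

test_that("adjusted variant zeroes planned same-day discharges", {
  enc <- data.frame(case_id = "c1", day_index = 2L, surgery_type = "A",
                    los_days = 0L, planned_same_day_discharge = TRUE)
  cal <- generate_calendar(6, 0)
  adj <- census_variant(enc, cal, "adjusted", predicted_los = 3)
  expect_equal(adj$value, rep(0, 6))
  pred <- census_variant(enc, cal, "predicted", predicted_los = 3)
  expect_equal(sum(pred$value), 3)
})

test_that("exogenous assembly respects information cutoffs and audits sources", {
  cal <- generate_calendar(60, 0, holidays = c(10L, 40L))
  set.seed(60)
  data <- list(holidays = as.numeric(cal$is_holiday),
               counts = as.numeric(50 + (0:59) %% 7 + rpois(60, 4)),
               observed_census = as.numeric(30 + (0:59) %% 5),
               predicted_census = as.numeric(29 + (0:59) %% 5))

  # calendar-known: holidays available arbitrarily far ahead
  ex <- assemble_exog("holidays", days = 45:52, cutoff = 20L, data = data)
  expect_equal(as.numeric(ex$X[, "holidays"]), data$holidays[46:53])
  expect_false(any(ex$audit$violation))

  # lagged counts beyond the cutoff are forecast-fed and flagged
  ex2 <- assemble_exog("surgery_count_lag7", days = c(25L, 35L), cutoff = 24L,
                       data = data)
  expect_equal(ex2$audit$forecast_fed, c(FALSE, TRUE))
  expect_equal(unname(ex2$X[1, 1]), data$counts[19])  # day 18, observed
  expect_true(is.finite(unname(ex2$X[2, 1])))         # day 28, forecast-fed

  # schedule-known census arrays are available at the target day
  ex3 <- assemble_exog("predicted_census", days = 30L, cutoff = 29L,
                       data = data)
  expect_equal(unname(ex3$X[1, 1]), data$predicted_census[31])
  expect_equal(ex3$audit$class, "schedule")

  # observed census beyond the cutoff is a leak
  expect_error(assemble_exog("observed_census", days = 30L, cutoff = 29L,
                             data = data),
               class = "surgecast_leak_error")
  ex4 <- assemble_exog("observed_census", days = 30L, cutoff = 29L,
                       data = data, allow_future_exog = TRUE)
  expect_true(any(ex4$audit$violation))

  expect_error(assemble_exog("nope", days = 1L, cutoff = 0L, data = data),
               "unknown exogenous")
})

test_that("deterministic weekly census is forecast exactly at long term", {
  pattern <- c(30, 32, 34, 31, 28, 12, 8)
  cal <- generate_calendar(140, 0)
  census <- daily_series(rep(pattern, 20), calendar = cal)
  counts <- daily_series(rep(100, 140), calendar = cal)
  ev <- run_census_model(census, counts, cal, model = "sarimax",
                         spec = sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                         protocol = "long_term", test_start = 105L,
                         test_end = 139L)
  expect_equal(ev$rmse, 0, tolerance = 1e-6)
  expect_equal(ev$n, 35L)
  expect_true(audit_pass(ev))
})

test_that("the OLS leak canary is blocked by the cutoff audit", {
  sim <- generate_encounters(tiny_gen_config(13))
  cal <- sim$calendar
  census <- census_variant(sim$encounters, cal, "observed")
  counts <- build_daily_counts(sim$encounters, cal)
  expect_error(
    run_census_model(census, counts, cal, model = "ols",
                     exog_features = "observed_census",
                     protocol = "same_day", test_start = 115L,
                     test_end = 149L),
    class = "surgecast_leak_error")
  # with the escape hatch the run completes trivially but the audit fails
  ev <- run_census_model(census, counts, cal, model = "ols",
                         exog_features = "observed_census",
                         protocol = "same_day", test_start = 115L,
                         test_end = 149L, allow_future_exog = TRUE)
  expect_false(audit_pass(ev))
  expect_lt(ev$rmse, 1e-6)  # regressing the target on itself
})

test_that("OLS and VAR protocols produce finite scored forecasts", {
  sim <- generate_encounters(tiny_gen_config(14))
  cal <- sim$calendar
  census <- census_variant(sim$encounters, cal, "observed")
  counts <- build_daily_counts(sim$encounters, cal)
  set.seed(2)
  pl <- pmax(0, sim$encounters$los_days + rnorm(nrow(sim$encounters), 0, 0.6))
  exog_data <- list(predicted_census =
                      census_variant(sim$encounters, cal, "predicted",
                                     predicted_los = pl)$value)
  ols <- run_census_model(census, counts, cal, model = "ols",
                          exog_features = "predicted_census",
                          exog_data = exog_data, protocol = "two_week",
                          test_start = 115L, test_end = 149L)
  expect_true(is.finite(ols$rmse))
  expect_equal(ols$n, 35L)
  expect_true(audit_pass(ols))

  var_ev <- run_census_model(census, counts, cal, model = "var",
                             exog_features = "holidays",
                             protocol = "long_term", test_start = 115L,
                             test_end = 149L)
  expect_true(is.finite(var_ev$rmse))
  expect_true(audit_pass(var_ev))
})

test_that("relative error report is the plain quotient", {
  ev <- structure(list(rmse = 22.67,
                       forecasts = data.frame(actual = c(700, 839, 820))),
                  class = "surgecast_eval")
  rep1 <- relative_error_report(ev, 839)
  expect_equal(rep1$relative_rmse_pct, 100 * 22.67 / 839)
  expect_equal(rep1$max_observed_census, 839)

  ev$rmse <- 0
  expect_equal(relative_error_report(ev, 839)$relative_rmse_pct, 0)
  ev$rmse <- 839
  expect_equal(relative_error_report(ev, 839)$relative_rmse_pct, 100)
  expect_error(relative_error_report(ev, 0), "positive")
})
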