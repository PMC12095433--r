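# Shared fixtures and independent oracles for the test suite.
#
# Heavy per-seed pipeline runs are memoized in `.fixture_cache` so that
# several test files can score the same simulated hospital years without
# recomputing them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Scaled-down hospital year used for evaluation experiments: volume means at
# one fifth of the defaults (same weekday:weekend:holiday proportions), a
# 300-code vocabulary and a stronger comorbidity effect concentrated in the
# top 40 codes so the reduced case count still carries clear LOS signal.
test_gen_config <- function(seed, ...) {
  defaults <- list(
    n_days = 365L,
    weekday_volume_mean = 64, weekend_volume_mean = 34,
    holiday_volume_mean = 24,
    n_surgery_types = 40L, n_codes = 300L,
    comorbidity_count_law = list(mean = 8, sd = 6, min = 1L, max = 40L),
    comorbidity_effect_codes = 40L, comorbidity_los_effect = 0.5,
    seed = seed
  )
  do.call(gen_config, utils::modifyList(defaults, list(...), keep.null = TRUE))
}

test_forest_spec <- function(seed) {
  forest_spec(n_trees = 50L, seed = seed + 500L)
}

# Tiny hospital year for fast structural tests.
tiny_gen_config <- function(seed, ...) {
  defaults <- list(
    n_days = 150L,
    weekday_volume_mean = 30, weekend_volume_mean = 15,
    holiday_volume_mean = 10, holidays = c(3L, 66L, 129L),
    n_surgery_types = 15L, n_codes = 80L,
    comorbidity_count_law = list(mean = 6, sd = 4, min = 1L, max = 30L),
    comorbidity_effect_codes = 20L, comorbidity_los_effect = 0.5,
    seed = seed
  )
  do.call(gen_config, utils::modifyList(defaults, list(...), keep.null = TRUE))
}

# Tiny end-to-end pipeline configuration (150-day year, 80/35/35 split).
tiny_pipeline_config <- function(seed = 17) {
  pipeline_config(
    generator = tiny_gen_config(seed),
    split = split_spec(80L, 115L, 150L),
    top_n = 40L, k = 4L,
    forest = forest_spec(n_trees = 15L, seed = seed),
    importance_repeats = 0L
  )
}

# Double-loop census oracle: one bed per case per occupied night.
census_oracle <- function(day_index, los, n_days) {
  census <- numeric(n_days)
  l <- floor(los + 0.5)
  for (i in seq_along(day_index)) {
    if (l[i] <= 0) next
    for (night in day_index[i] + 0:(l[i] - 1L)) {
      if (night < n_days) census[night + 1L] <- census[night + 1L] + 1
    }
  }
  census
}

# Simulate from a pure seasonal-MA(1) model after one seasonal difference:
# (1 - B^7) x_t = e_t + theta * e_{t-7}.
simulate_seasonal_ma <- function(n, theta, period = 7L, sd = 1, seed = 1L) {
  set.seed(seed)
  e <- rnorm(n + period, sd = sd)
  w <- e[(period + 1):(n + period)] + theta * e[1:n]
  x <- numeric(n)
  x[1:period] <- w[1:period]
  for (t in (period + 1):n) x[t] <- x[t - period] + w[t]
  x
}

# One full per-seed evaluation on the scaled hospital year: validation-stage
# forest vs baseline, final-stage per-case predictions, and the four
# same-day census runs (perfect / predicted / adjusted / per-type-mean).
scaled_seed_run <- function(seed) {
  cached(sprintf("seed_run_%d", seed), {
    cfg <- test_gen_config(seed)
    sim <- generate_encounters(cfg)
    spec <- split_spec(225L, 295L, cfg$n_days)
    splits <- chronological_split(sim$encounters, spec)
    trainval <- rbind(splits$train, splits$val)

    fit_stage <- function(fit_window, eval_window) {
      imp <- fit_imputer(fit_window)
      fitw <- apply_imputer(imp, fit_window)
      evw <- apply_imputer(imp, eval_window)
      vocab <- suppressWarnings(select_top_n_codes(fitw, 150L))
      m_fit <- build_onehot_matrix(fitw, vocab)
      m_ev <- build_onehot_matrix(evw, vocab)
      dec <- fit_decomposition(m_fit, "truncated_svd", 8L)
      hist_los <- compute_historic_mean_los(fitw)
      schema <- los_schema(fitw, k = 8L, score_prefix = dec$prefix)
      tr <- assemble_los_features(fitw, predict(dec, m_fit), hist_los, schema)
      ev <- assemble_los_features(evw, predict(dec, m_ev), hist_los, schema)
      forest <- fit_los_forest(tr$X, tr$y, test_forest_spec(seed))
      pred <- predict_los(forest, ev$X)
      list(historic = hist_los, eval_window = evw, predictions = pred,
           rmse = evaluate_los(pred, ev$y)$rmse,
           baseline_rmse = evaluate_los(
             predict_mean_los_baseline(hist_los, evw$surgery_type), ev$y)$rmse)
    }
    val_stage <- fit_stage(splits$train, splits$val)
    all_enc <- rbind(trainval, splits$test)
    final <- fit_stage(trainval, all_enc)

    cal <- sim$calendar
    pl <- final$predictions
    census_obs <- census_variant(final$eval_window, cal, "observed")
    counts <- build_daily_counts(sim$encounters, cal)
    exog_data <- list(
      predicted_census = census_variant(final$eval_window, cal, "predicted",
                                        predicted_los = pl)$value,
      adjusted_census = census_variant(final$eval_window, cal, "adjusted",
                                       predicted_los = pl)$value,
      perfect_census = census_variant(final$eval_window, cal, "perfect")$value,
      surgery_mean_census = census_variant(final$eval_window, cal,
                                           "surgery_mean",
                                           historic = final$historic)$value
    )
    same_day_rmse <- vapply(
      c("perfect_census", "predicted_census", "adjusted_census",
        "surgery_mean_census"),
      function(f) {
        run_census_model(census_obs, counts, cal, model = "sarimax",
                         spec = sarimax_spec(0, 0, 0, 1, 1, 0, 7),
                         exog_features = f, exog_data = exog_data,
                         protocol = "same_day",
                         test_start = spec$val_end_day,
                         test_end = cfg$n_days - 1L)$rmse
      }, numeric(1))

    # type-level recovery: model-implied vs ground-truth mean LOS per type
    by_type <- tapply(pl, final$eval_window$surgery_type, mean)
    n_type <- table(final$eval_window$surgery_type)
    big <- names(n_type)[n_type >= 200L]
    truth_mean <- sim$truth$per_type_los$expected_los[
      match(big, sim$truth$per_type_los$surgery_type)]
    type_cor <- if (length(big) >= 5L) {
      cor(by_type[big], truth_mean, method = "spearman")
    } else NA_real_

    list(val_rmse = val_stage$rmse, baseline_rmse = val_stage$baseline_rmse,
         same_day_rmse = same_day_rmse, type_cor = type_cor,
         n_big_types = length(big))
  })
}

# Long-term census forecasts with and without the holiday regressor on the
# scaled hospital year (no LOS model involved).
holiday_benefit_run <- function(seed) {
  cached(sprintf("holiday_run_%d", seed), {
    cfg <- test_gen_config(seed)
    sim <- generate_encounters(cfg)
    cal <- sim$calendar
    census_obs <- census_variant(sim$encounters, cal, "observed")
    counts <- build_daily_counts(sim$encounters, cal)
    with_hol <- run_census_model(census_obs, counts, cal, model = "sarimax",
                                 spec = sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                                 exog_features = "holidays",
                                 protocol = "long_term", test_start = 295L,
                                 test_end = cfg$n_days - 1L)
    without <- run_census_model(census_obs, counts, cal, model = "sarimax",
                                spec = sarimax_spec(0, 0, 0, 0, 1, 1, 7),
                                protocol = "long_term", test_start = 295L,
                                test_end = cfg$n_days - 1L)
    c(with_holidays = with_hol$rmse, without = without$rmse)
  })
}

# Daily counts of a default-configuration hospital year (cached per seed;
# only the count series is retained).
default_counts_run <- function(seed) {
  cached(sprintf("default_counts_%d", seed), {
    sim <- generate_encounters(gen_config(seed = seed))
    list(counts = build_daily_counts(sim$encounters, sim$calendar),
         holidays = as.numeric(sim$calendar$is_holiday))
  })
}
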