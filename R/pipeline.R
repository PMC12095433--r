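#' End-to-end pipeline configuration
#'
#' Bundles the per-stage settings: the synthetic generator (or a path to an
#' encounter CSV in the same schema), the chronological split, preprocessing
#' choices (vocabulary size `top_n`, component count `k`, reduction method),
#' the LOS forest, the volume forecaster, and the census grid. Seeds are
#' namespaced per stage so stages can be varied independently.
#'
#' @param generator a [gen_config()] (ignored when `encounters_csv` is set).
#' @param encounters_csv optional path to an encounter CSV to ingest instead
#'   of simulating.
#' @param split a [split_spec()].
#' @param top_n comorbidity vocabulary size.
#' @param k number of decomposition components.
#' @param decomp_method reduction method (see [fit_decomposition()]).
#' @param forest a [forest_spec()].
#' @param volume_spec [sarimax_spec()] for the daily-count forecaster.
#' @param apply_missingness inject the generator's configured missingness
#'   before preprocessing (exercises the imputation rules).
#' @param capacity_reference optional bed denominator for the relative-error
#'   report; defaults to the maximum observed census.
#' @param importance_repeats permutation-importance repeats (0 skips the
#'   importance computation).
#' @param missingness_seed,importance_seed stage seeds.
#' @return an object of class `surgecast_pipeline_config`.
#' @export
pipeline_config <- function(generator = gen_config(),
                            encounters_csv = NULL,
                            split = split_spec(225L, 295L, generator$n_days),
                            top_n = 1750L,
                            k = 12L,
                            decomp_method = "truncated_svd",
                            forest = forest_spec(),
                            volume_spec = sarimax_spec(0, 0, 0, 0, 1, 1, 7,
                                                       exog_names = "holidays"),
                            apply_missingness = TRUE,
                            capacity_reference = NULL,
                            importance_repeats = 10L,
                            missingness_seed = 271L,
                            importance_seed = 42L) {
  stopifnot(inherits(generator, "surgecast_config"),
            inherits(split, "surgecast_split"),
            inherits(forest, "surgecast_forest_spec"),
            inherits(volume_spec, "surgecast_sarimax_spec"))
  if (is.null(forest)) stop("a forest spec is required", call. = FALSE)
  structure(list(generator = generator, encounters_csv = encounters_csv,
                 split = split, top_n = check_count(top_n, "top_n"),
                 k = check_count(k, "k"), decomp_method = decomp_method,
                 forest = forest, volume_spec = volume_spec,
                 apply_missingness = isTRUE(apply_missingness),
                 capacity_reference = capacity_reference,
                 importance_repeats = check_count(importance_repeats,
                                                  "importance_repeats", 0L),
                 missingness_seed = missingness_seed,
                 importance_seed = importance_seed),
            class = "surgecast_pipeline_config")
}

#' Run the full forecasting pipeline
#'
#' Stages, in dependency order: simulate (or ingest) the encounter table;
#' exclude unusable records; split chronologically; fit imputation,
#' vocabulary, decomposition, historic-LOS and forest on the training window
#' and evaluate on validation; refit all fitted statistics on train +
#' validation and evaluate on the held-out test window; build predicted /
#' adjusted / perfect / per-type-mean census arrays from per-case LOS
#' predictions; evaluate the rolling one-week-ahead volume forecaster; run
#' the census model grid; and render the report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/JSON files.
#' @return a list of class `surgecast_run` with elements `los`, `volume`,
#'   `census`, `grid`, `report`, `relative_error` and `manifest` (config
#'   hash, per-stage output digests and wall times; identical config gives
#'   identical digests).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "surgecast_pipeline_config"))
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, wall = proc.time()[["elapsed"]] - t0)
  }
  timings <- list()

  # --- stage: simulate / ingest --------------------------------------------
  st <- t_stage({
    if (!is.null(config$encounters_csv)) {
      enc <- read_encounters(config$encounters_csv)
      cal <- generate_calendar(config$split$n_days,
                               config$generator$day0_weekday,
                               config$generator$holidays)
      list(encounters = enc, calendar = cal, truth = NULL)
    } else {
      generate_encounters(config$generator)
    }
  })
  sim <- st$value; timings$simulate <- st$wall
  enc <- sim$encounters
  if (config$apply_missingness && is.null(config$encounters_csv)) {
    enc <- inject_missingness(enc, config$generator$missingness_rates,
                              seed = config$missingness_seed)
  }

  # --- stage: preprocess ---------------------------------------------------
  st <- t_stage({
    excl <- exclude_invalid(enc)
    splits <- chronological_split(excl$encounters, config$split)
    trainval <- rbind(splits$train, splits$val)
    list(excl = excl, splits = splits, trainval = trainval)
  })
  pp <- st$value; timings$preprocess <- st$wall
  splits <- pp$splits

  # --- stage: LOS model ----------------------------------------------------
  st <- t_stage({
    fit_stage <- function(fit_window, eval_window) {
      imp <- fit_imputer(fit_window)
      fitw <- apply_imputer(imp, fit_window)
      evw <- apply_imputer(imp, eval_window)
      vocab <- suppressWarnings(select_top_n_codes(fitw, config$top_n))
      m_fit <- build_onehot_matrix(fitw, vocab)
      m_ev <- build_onehot_matrix(evw, vocab)
      dec <- fit_decomposition(m_fit, config$decomp_method, config$k)
      hist_los <- compute_historic_mean_los(fitw)
      schema <- los_schema(fitw, k = config$k, score_prefix = dec$prefix)
      tr <- assemble_los_features(fitw, predict(dec, m_fit), hist_los, schema)
      ev <- assemble_los_features(evw, predict(dec, m_ev), hist_los, schema)
      forest <- fit_los_forest(tr$X, tr$y, config$forest)
      pred <- predict_los(forest, ev$X)
      list(imputer = imp, vocab = vocab, decomp = dec, historic = hist_los,
           schema = schema, forest = forest, eval_window = evw,
           features = ev, predictions = pred,
           evaluation = evaluate_los(pred, ev$y),
           baseline = evaluate_los(
             predict_mean_los_baseline(hist_los, evw$surgery_type), ev$y),
           n_features = ncol(tr$X))
    }
    val_stage <- fit_stage(splits$train, splits$val)
    test_stage <- fit_stage(pp$trainval, splits$test)
    importance <- if (config$importance_repeats > 0L) {
      los_permutation_importance(val_stage$forest, val_stage$features$X,
                                 val_stage$features$y,
                                 n_repeats = config$importance_repeats,
                                 seed = config$importance_seed)
    } else NULL
    list(val = val_stage, test = test_stage, importance = importance)
  })
  los <- st$value; timings$fit_los <- st$wall

  # --- stage: per-case predictions for the whole calendar ------------------
  st <- t_stage({
    final <- los$test
    all_enc <- apply_imputer(final$imputer, rbind(pp$trainval, splits$test))
    m_all <- build_onehot_matrix(all_enc, final$vocab)
    feats <- assemble_los_features(all_enc, predict(final$decomp, m_all),
                                   final$historic, final$schema)
    data.frame(case_id = all_enc$case_id,
               day_index = all_enc$day_index,
               surgery_type = all_enc$surgery_type,
               planned_same_day_discharge = all_enc$planned_same_day_discharge,
               los_days = all_enc$los_days,
               predicted_los_days = predict_los(final$forest, feats$X))
  })
  case_pred <- st$value; timings$predict_los <- st$wall

  # --- stage: volume forecaster -------------------------------------------
  st <- t_stage({
    counts <- build_daily_counts(pp$excl$encounters, sim$calendar)
    acfrep <- correlogram(counts, max_lag = 30L)
    holid <- matrix(as.numeric(sim$calendar$is_holiday), ncol = 1,
                    dimnames = list(NULL, "holidays"))
    roll <- rolling_forecast(counts, config$volume_spec, exog = holid,
                             origin_start = config$split$val_end_day - 1L,
                             step = 7L, horizon = 7L)
    list(counts = counts, correlogram = acfrep, rolling = roll)
  })
  volume <- st$value; timings$forecast_volume <- st$wall

  # --- stage: census grid --------------------------------------------------
  st <- t_stage({
    cal <- sim$calendar
    enc_all <- rbind(pp$trainval, splits$test)
    enc_all <- apply_imputer(los$test$imputer, enc_all)
    pl <- case_pred$predicted_los_days[match(enc_all$case_id,
                                             case_pred$case_id)]
    census_obs <- census_variant(enc_all, cal, "observed")
    exog_data <- list(
      predicted_census = census_variant(enc_all, cal, "predicted",
                                        predicted_los = pl)$value,
      adjusted_census = census_variant(enc_all, cal, "adjusted",
                                       predicted_los = pl)$value,
      perfect_census = census_variant(enc_all, cal, "perfect")$value,
      surgery_mean_census = census_variant(enc_all, cal, "surgery_mean",
                                           historic = los$test$historic)$value
    )
    grid <- run_table2_grid(census_obs, volume$counts, cal, exog_data,
                            test_start = config$split$val_end_day,
                            test_end = config$split$n_days - 1L)
    best_same_day <- grid$evals[[which(grid$summary$time_point == "same_day" &
                                         grid$summary$exog == "adjusted_census")]]
    cap <- config$capacity_reference %||% max(census_obs$value)
    list(observed = census_obs, exog_data = exog_data, grid = grid,
         relative_error = relative_error_report(best_same_day, cap))
  })
  census <- st$value; timings$forecast_beds <- st$wall

  report <- render_report(census$grid, los$test$evaluation, volume$rolling)
  manifest <- list(
    config_hash = hash_object(config),
    package_version = as.character(utils::packageVersion("surgecast")),
    output_digests = list(
      encounters = hash_object(sim$encounters),
      case_predictions = hash_object(case_pred),
      grid_summary = hash_object(census$grid$summary),
      los_rmse = los$test$evaluation$rmse,
      volume_rmse = volume$rolling$rmse
    ),
    wall_time_s = timings,
    warnings = character()
  )
  run <- structure(list(
    sim = sim, exclusions = pp$excl$report, splits = splits, los = los,
    case_predictions = case_pred, volume = volume, census = census,
    grid = census$grid, report = report,
    relative_error = census$relative_error, manifest = manifest
  ), class = "surgecast_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_encounters(run$sim$encounters, file.path(out_dir, "encounters.csv"))
  write_calendar(run$sim$calendar, file.path(out_dir, "calendar.csv"))
  utils::write.csv(run$case_predictions,
                   file.path(out_dir, "predicted_los.csv"), row.names = FALSE)
  write_series(run$volume$counts, file.path(out_dir, "daily_counts.csv"))
  write_series(run$census$observed, file.path(out_dir, "census_observed.csv"))
  utils::write.csv(run$grid$summary, file.path(out_dir, "grid_summary.csv"),
                   row.names = FALSE)
  write_report_json(run$report$json, file.path(out_dir, "report.json"))
  writeLines(run$report$text, file.path(out_dir, "report.txt"))
  write_report_json(run$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Render pipeline results as text and JSON reports
#'
#' @param grid a `surgecast_grid` (may be empty).
#' @param los_eval a `surgecast_los_eval` or `NULL`.
#' @param volume_eval a `surgecast_rolling` or `NULL`.
#' @return list with `text` (character lines; numbers at 2 decimals) and
#'   `json` (full-precision list ready for serialization).
#' @export
render_report <- function(grid, los_eval = NULL, volume_eval = NULL) {
  if (is.null(grid) && is.null(los_eval) && is.null(volume_eval)) {
    stop("at least one evaluation is required", call. = FALSE)
  }
  lines <- character()
  json <- list()
  if (!is.null(los_eval)) {
    lines <- c(lines, sprintf("LOS model: RMSE %.2f days, MAE %.2f days",
                              los_eval$rmse, los_eval$mae))
    json$los <- list(rmse_days = los_eval$rmse, mae_days = los_eval$mae,
                     strata = los_eval$strata)
  }
  if (!is.null(volume_eval)) {
    lines <- c(lines, sprintf("Volume forecast (rolling 1-week-ahead): RMSE %.2f cases",
                              volume_eval$rmse))
    json$volume <- list(rmse_cases = volume_eval$rmse,
                        n_forecasts = nrow(volume_eval$forecasts),
                        n_failures = nrow(volume_eval$failures))
  }
  header <- sprintf("%-10s %-28s %-38s %8s %8s",
                    "Horizon", "Model", "Exogenous variables", "RMSE", "SD")
  lines <- c(lines, "", header)
  if (is.null(grid) || nrow(grid$summary) == 0L) {
    warning("census grid is empty; report contains headers only",
            call. = FALSE)
  } else {
    s <- grid$summary
    lines <- c(lines, sprintf("%-10s %-28s %-38s %8.2f %8.2f",
                              s$time_point, s$model, s$exog, s$rmse, s$sd))
    json$grid <- s
  }
  list(text = lines, json = json)
}

#' @export
print.surgecast_run <- function(x, ...) {
  writeLines(x$report$text)
  invisible(x)
}
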