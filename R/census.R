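# Bed-census construction and the model x horizon forecasting grid.
#
# Census convention: a case with surgery day d and LOS l days occupies one
# bed on nights d, d+1, ..., d+l-1; l = 0 (same-day discharge) occupies no
# bed; nights beyond the calendar are truncated. This yields the exact
# conservation identity sum_d census(d) = sum_cases min(l, n_days - d).

#' Build a daily bed-census array from per-case stays
#'
#' @param day_index integer surgery day per case (0-based).
#' @param los per-case length of stay in days (nonnegative; may be
#'   fractional when `round = FALSE`).
#' @param n_days calendar length.
#' @param round round fractional LOS half-up per case before aggregation
#'   (default); with `FALSE`, a fractional stay contributes its fractional
#'   part to the final night.
#' @return numeric census vector of length `n_days`.
#' @export
build_census <- function(day_index, los, n_days, round = TRUE) {
  n_days <- check_count(n_days, "n_days")
  stopifnot(length(day_index) == length(los))
  if (any(is.na(los)) || any(los < 0)) {
    stop("LOS values must be nonnegative and non-missing", call. = FALSE)
  }
  if (length(day_index) && (any(day_index < 0) || any(day_index >= n_days))) {
    stop("day_index outside [0, n_days)", call. = FALSE)
  }
  l <- if (round) round_half_up(los) else los
  delta <- numeric(n_days + 1L)
  full <- pmin(floor(l), n_days - day_index)
  has <- full > 0
  if (any(has)) {
    s <- as.integer(day_index[has] + 1L)
    e <- as.integer(day_index[has] + full[has] + 1L)
    delta <- tabulate(s, n_days + 1L) - tabulate(e, n_days + 1L)
    delta <- as.numeric(delta)
  }
  if (!round) {
    frac <- l - floor(l)
    fday <- day_index + floor(l)
    ok <- frac > 0 & fday < n_days
    if (any(ok)) {
      fs <- tapply(frac[ok], fday[ok] + 1L, sum)
      delta[as.integer(names(fs))] <- delta[as.integer(names(fs))] + fs
      fe <- as.integer(names(fs)) + 1L
      delta[fe] <- delta[fe] - fs
    }
  }
  cumsum(delta)[seq_len(n_days)]
}

#' Census variants from different LOS sources
#'
#' Builds the census series whose per-case stay is, by variant: `observed`
#' the recorded LOS; `predicted` the LOS-model prediction; `adjusted` the
#' prediction overridden to 0 for cases flagged as planned same-day
#' discharge; `perfect` the actual LOS (an oracle bound, identical to
#' `observed` by construction); `surgery_mean` the per-type historic mean
#' LOS.
#'
#' @param encounters encounter data frame.
#' @param calendar a `surgecast_calendar`.
#' @param variant one of `"observed"`, `"predicted"`, `"adjusted"`,
#'   `"perfect"`, `"surgery_mean"`.
#' @param predicted_los per-case predicted LOS (required for `predicted` and
#'   `adjusted`).
#' @param historic [compute_historic_mean_los()] output (required for
#'   `surgery_mean`).
#' @param round round fractional stays half-up (see [build_census()]).
#' @return a `surgecast_series` named `census_<variant>`.
#' @export
census_variant <- function(encounters, calendar,
                           variant = c("observed", "predicted", "adjusted",
                                       "perfect", "surgery_mean"),
                           predicted_los = NULL, historic = NULL,
                           round = TRUE) {
  variant <- match.arg(variant)
  los <- switch(variant,
    observed = ,
    perfect = encounters$los_days,
    predicted = {
      if (is.null(predicted_los)) stop("predicted_los required", call. = FALSE)
      predicted_los
    },
    adjusted = {
      if (is.null(predicted_los)) stop("predicted_los required", call. = FALSE)
      ifelse(encounters$planned_same_day_discharge, 0, predicted_los)
    },
    surgery_mean = {
      if (is.null(historic)) stop("historic mean LOS required", call. = FALSE)
      predict_mean_los_baseline(historic, encounters$surgery_type)
    }
  )
  daily_series(build_census(encounters$day_index, los, nrow(calendar),
                            round = round),
               calendar = calendar, name = paste0("census_", variant))
}

# --- exogenous feature assembly with information-cutoff audit ---------------

exog_feature_classes <- c(
  holidays = "calendar",
  surgery_count_lag7 = "observed",
  predicted_census = "schedule",
  adjusted_census = "schedule",
  perfect_census = "schedule",
  surgery_mean_census = "schedule",
  observed_census = "observed"
)

#' Assemble an exogenous matrix for a set of forecast days under a cutoff
#'
#' Every exogenous value dated after the information cutoff must come from a
#' permitted source: calendar-known features (holidays), schedule-known
#' features (the census arrays derived from the surgical schedule and
#' pre-operating-day LOS predictions), or a forecast from the volume model
#' (`surgery_count_lag7` values whose source day post-dates the cutoff are
#' forecast-fed and flagged as such). Requesting an observed value beyond
#' the cutoff raises a `surgecast_leak_error` unless `allow_future_exog` is
#' set, in which case the value is taken and the audit records a violation.
#'
#' @param features character vector of feature names (see Details).
#' @param days integer day indices the rows correspond to.
#' @param cutoff latest day whose observed data may be consumed.
#' @param data named list with `holidays` (0/1 vector), `counts`, and any
#'   schedule census arrays used, all full-length day-indexed vectors.
#' @param volume_spec SARIMAX spec used to forecast future surgery counts.
#' @param allow_future_exog permit observed values beyond the cutoff (audit
#'   still marks them as violations).
#' @param cache optional environment memoizing volume-model fits per cutoff.
#' @return list with `X` (matrix, one row per day) and `audit` (data frame:
#'   `target_day`, `feature`, `source_day`, `class`, `cutoff`,
#'   `forecast_fed`, `violation`).
#' @export
assemble_exog <- function(features, days, cutoff, data,
                          volume_spec = sarimax_spec(0, 0, 0, 0, 1, 1, 7,
                                                     exog_names = "holidays"),
                          allow_future_exog = FALSE,
                          cache = new.env(parent = emptyenv()),
                          audit = TRUE) {
  empty_audit <- data.frame(target_day = integer(), feature = character(),
                            source_day = integer(), class = character(),
                            cutoff = integer(), forecast_fed = logical(),
                            violation = logical())
  if (!length(features)) return(list(X = NULL, audit = empty_audit))
  unknown <- setdiff(features, names(exog_feature_classes))
  if (length(unknown)) {
    stop(sprintf("unknown exogenous feature(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  days <- as.integer(days)
  nd <- length(days)
  # expanding-window volume forecast from the cutoff, memoized per cutoff
  forecast_counts <- function(h_needed) {
    fit_key <- sprintf("fit%d", cutoff)
    m <- cache[[fit_key]]
    if (is.null(m)) {
      m <- fit_sarimax(data$counts[seq_len(cutoff + 1L)], volume_spec,
                       xreg = matrix(data$holidays[seq_len(cutoff + 1L)],
                                     ncol = 1))
      cache[[fit_key]] <- m
    }
    fc_key <- sprintf("fc%d_%d", cutoff, h_needed)
    fc <- cache[[fc_key]]
    if (is.null(fc)) {
      fc <- forecast_sarimax(m, h_needed,
                             newxreg = matrix(
                               data$holidays[cutoff + 1L + seq_len(h_needed)],
                               ncol = 1))
      cache[[fc_key]] <- fc
    }
    fc
  }
  cols <- vector("list", length(features))
  audits <- vector("list", length(features))
  for (fi in seq_along(features)) {
    f <- features[fi]
    cls <- exog_feature_classes[[f]]
    src <- days
    fed <- rep(FALSE, nd)
    viol <- rep(FALSE, nd)
    if (f == "holidays") {
      v <- data$holidays[days + 1L]
    } else if (f == "surgery_count_lag7") {
      src <- pmax(days - 7L, 0L)
      fed <- src > cutoff
      v <- numeric(nd)
      v[!fed] <- data$counts[src[!fed] + 1L]
      if (any(fed)) {
        fc <- forecast_counts(max(src[fed]) - cutoff)
        v[fed] <- fc[src[fed] - cutoff]
      }
    } else if (cls == "schedule") {
      vec <- data[[f]]
      if (is.null(vec)) {
        stop(sprintf("schedule feature '%s' unavailable for day %d", f,
                     days[1L]), call. = FALSE)
      }
      v <- vec[days + 1L]
      if (anyNA(v)) {
        stop(sprintf("schedule feature '%s' unavailable for day %d", f,
                     days[which(is.na(v))[1L]]), call. = FALSE)
      }
    } else { # observed census used directly as a regressor
      viol <- days > cutoff
      if (any(viol) && !allow_future_exog) {
        stop(structure(class = c("surgecast_leak_error", "error", "condition"),
                       list(message = sprintf(
                         "feature '%s' at day %d post-dates cutoff %d and is not forecastable",
                         f, days[which(viol)[1L]], cutoff), call = NULL)))
      }
      v <- (data$observed_census %||% data$census)[days + 1L]
    }
    cols[[fi]] <- v
    if (audit) {
      audits[[fi]] <- data.frame(target_day = days, feature = f,
                                 source_day = src, class = cls,
                                 cutoff = cutoff, forecast_fed = fed,
                                 violation = viol)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- features
  list(X = X, audit = if (audit) do.call(rbind, audits) else empty_audit)
}

#' Did a forecasting run respect its information cutoffs?
#'
#' Walks the run's audit log and checks that no consumed exogenous value
#' post-dates its cutoff unless it is calendar-known, schedule-known or
#' forecast-fed.
#'
#' @param evaluation a `surgecast_eval` (or anything with an `audit` field).
#' @return `TRUE` when no violations were logged.
#' @export
audit_pass <- function(evaluation) {
  aud <- evaluation$audit
  if (is.null(aud) || nrow(aud) == 0L) return(TRUE)
  !any(aud$violation)
}

# --- VAR --------------------------------------------------------------------

# VAR(p) fitted by per-equation OLS on lagged endogenous values plus
# exogenous regressors; forecasts recurse on the model's own predictions.
fit_var <- function(Y, p = 7L, exog = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n <= p + 2L) stop("series too short for VAR fit", call. = FALSE)
  rows <- (p + 1L):n
  lags <- do.call(cbind, lapply(seq_len(p), function(l) Y[rows - l, , drop = FALSE]))
  design <- cbind(1, lags)
  if (!is.null(exog)) design <- cbind(design, as.matrix(exog)[rows, , drop = FALSE])
  coef <- tryCatch(qr.coef(qr(design), Y[rows, , drop = FALSE]),
                   error = function(e) {
                     stop(structure(class = c("surgecast_fit_error", "error",
                                              "condition"),
                                    list(message = paste("VAR fit failed:",
                                                         conditionMessage(e)),
                                         call = NULL)))
                   })
  coef[is.na(coef)] <- 0
  list(coef = coef, p = p, k = ncol(Y), n_exog = if (is.null(exog)) 0L else ncol(exog))
}

forecast_var <- function(model, Y, h, future_exog = NULL) {
  p <- model$p
  hist <- as.matrix(Y)
  out <- matrix(NA_real_, h, model$k)
  for (s in seq_len(h)) {
    m <- nrow(hist)
    lags <- as.numeric(t(hist[m - seq_len(p) + 1L, , drop = FALSE]))
    x <- c(1, lags)
    if (model$n_exog > 0L) x <- c(x, as.numeric(future_exog[s, ]))
    pred <- as.numeric(x %*% model$coef)
    out[s, ] <- pred
    hist <- rbind(hist, pred)
  }
  out
}

# --- model x protocol runner ------------------------------------------------

#' Run one census forecasting model under one horizon protocol
#'
#' Protocols define the information cutoff for each forecast day `t` in the
#' test window: `long_term` fits once on all data before the test window and
#' issues a static multi-step forecast across it (cutoff = training end);
#' `two_week` refits at every origin and scores only day `t` forecast from
#' data up to `t - 14`; `same_day` refits daily and forecasts day `t` from
#' data up to `t - 1` plus schedule-known day-`t` exogenous values.
#'
#' @param census observed census `surgecast_series` (full calendar).
#' @param counts daily surgical count `surgecast_series` (full calendar).
#' @param calendar the `surgecast_calendar`.
#' @param model `"sarimax"`, `"ols"` or `"var"`.
#' @param spec a [sarimax_spec()] (SARIMAX only; its `exog_names` are taken
#'   from `exog_features`).
#' @param exog_features exogenous feature names (see [assemble_exog()]).
#' @param exog_data named list of schedule census arrays referenced by
#'   `exog_features`.
#' @param protocol `"long_term"`, `"two_week"` or `"same_day"`.
#' @param test_start,test_end day-index bounds (inclusive) of the evaluation
#'   window.
#' @param var_p VAR lag order.
#' @param allow_future_exog see [assemble_exog()].
#' @param label row label for reports.
#' @return an object of class `surgecast_eval` with per-day forecasts,
#'   `rmse` (beds), `sd` (standard deviation of absolute errors across
#'   forecast days), the audit log and any per-origin fit failures.
#' @export
run_census_model <- function(census, counts, calendar,
                             model = c("sarimax", "ols", "var"),
                             spec = NULL, exog_features = character(),
                             exog_data = list(),
                             protocol = c("long_term", "two_week", "same_day"),
                             test_start, test_end = NULL, var_p = 7L,
                             allow_future_exog = FALSE, label = NULL) {
  model <- match.arg(model)
  protocol <- match.arg(protocol)
  n_days <- nrow(calendar)
  test_end <- test_end %||% (n_days - 1L)
  stopifnot(test_start > 14L, test_end < n_days, test_start <= test_end)
  y <- census$value
  data <- c(list(holidays = as.numeric(calendar$is_holiday),
                 counts = counts$value, observed_census = y), exog_data)
  cache <- new.env(parent = emptyenv())
  if (model == "sarimax") {
    if (is.null(spec)) stop("a sarimax_spec is required", call. = FALSE)
    spec$exog_names <- exog_features
  }
  audit_all <- list()
  failures <- list()
  rows <- list()

  fit_days <- function(cutoff) seq_len(cutoff + 1L) # positions of days 0..cutoff

  one_origin <- function(cutoff, path_days, score_day) {
    # exog over the fitted window (historical, all <= cutoff by construction)
    hist_days <- 0:cutoff
    ex_hist <- if (length(exog_features)) {
      assemble_exog(exog_features, hist_days, cutoff, data,
                    allow_future_exog = TRUE, cache = cache,
                    audit = FALSE)$X
    } else NULL
    ex_path <- assemble_exog(exog_features, path_days, cutoff, data,
                             allow_future_exog = allow_future_exog,
                             cache = cache)
    audit_all[[length(audit_all) + 1L]] <<- ex_path$audit
    h <- length(path_days)
    fc <- if (model == "sarimax") {
      m <- fit_sarimax(y[fit_days(cutoff)], spec, xreg = ex_hist)
      forecast_sarimax(m, h, newxreg = ex_path$X)
    } else if (model == "ols") {
      df_fit <- data.frame(y = y[fit_days(cutoff)])
      if (!is.null(ex_hist)) df_fit <- cbind(df_fit, as.data.frame(ex_hist))
      lm_fit <- stats::lm(y ~ ., data = df_fit)
      newd <- if (is.null(ex_path$X)) {
        data.frame(row.names = seq_len(h))
      } else {
        as.data.frame(ex_path$X)
      }
      as.numeric(stats::predict(lm_fit, newdata = newd))
    } else {
      Y <- cbind(census = y[fit_days(cutoff)],
                 counts = data$counts[fit_days(cutoff)])
      vm <- fit_var(Y, p = var_p, exog = ex_hist)
      forecast_var(vm, Y, h, future_exog = ex_path$X)[, 1L]
    }
    keep <- match(score_day, path_days)
    data.frame(target_day = score_day, forecast = fc[keep],
               actual = y[score_day + 1L])
  }

  if (protocol == "long_term") {
    cutoff <- test_start - 1L
    res <- tryCatch(one_origin(cutoff, test_start:test_end,
                               test_start:test_end),
                    surgecast_fit_error = function(e) e,
                    surgecast_leak_error = function(e) stop(e))
    if (inherits(res, "error")) {
      failures[[1L]] <- data.frame(origin = cutoff,
                                   message = conditionMessage(res))
    } else {
      rows[[1L]] <- res
    }
  } else {
    lead <- if (protocol == "two_week") 14L else 1L
    for (t in test_start:test_end) {
      cutoff <- t - lead
      res <- tryCatch(one_origin(cutoff, (cutoff + 1L):t, t),
                      surgecast_fit_error = function(e) e,
                      surgecast_leak_error = function(e) stop(e))
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(origin = cutoff, message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }

  fc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_day = integer(), forecast = numeric(), actual = numeric())
  fc$error <- fc$forecast - fc$actual
  structure(list(
    label = label %||% sprintf("%s/%s", model, protocol),
    model = model,
    spec = if (model == "sarimax") sub(" \\+ .*$", "", format(spec))
           else toupper(model),
    exog_features = exog_features,
    protocol = protocol,
    forecasts = fc,
    rmse = if (nrow(fc)) rmse(fc$error) else NA_real_,
    sd = if (nrow(fc) > 1L) stats::sd(abs(fc$error)) else NA_real_,
    n = nrow(fc),
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(origin = integer(), message = character()),
    audit = if (length(audit_all)) do.call(rbind, audit_all) else
      data.frame(target_day = integer(), feature = character(),
                 source_day = integer(), class = character(),
                 cutoff = integer(), forecast_fed = logical(),
                 violation = logical())
  ), class = "surgecast_eval")
}

#' @export
print.surgecast_eval <- function(x, ...) {
  cat(sprintf("<surgecast_eval> %s | %s | exog: %s\n  RMSE %.2f beds, SD %.2f over %d days (%d failures)\n",
              x$protocol, x$spec,
              if (length(x$exog_features)) paste(x$exog_features, collapse = ", ")
              else "none",
              x$rmse, x$sd, x$n, nrow(x$failures)))
  invisible(x)
}

#' Run the census model grid across horizons
#'
#' Evaluates the standard model battery: at the long-term horizon a seasonal
#' ARIMA with and without the holiday regressor plus a VAR of census and
#' surgery counts; at the two-week horizon an OLS on the predicted-LOS
#' census, and SARIMAX variants using the predicted-LOS census or holidays
#' plus 7-day-lagged (forecast-fed) surgery counts; at the same-day horizon
#' SARIMAX with holidays and with the predicted, adjusted, perfect and
#' per-type-mean LOS census arrays (the last two being the lower/upper
#' information bounds).
#'
#' @param census observed census series.
#' @param counts daily count series.
#' @param calendar calendar.
#' @param exog_data named list with `predicted_census`, `adjusted_census`,
#'   `perfect_census`, `surgery_mean_census` vectors.
#' @param test_start,test_end evaluation window (inclusive day indices).
#' @param var_p VAR lag order.
#' @return an object of class `surgecast_grid`: list of `surgecast_eval`
#'   rows plus a `summary` data frame (time point, model, exogenous
#'   variables, RMSE, SD).
#' @export
run_table2_grid <- function(census, counts, calendar, exog_data,
                            test_start, test_end = NULL, var_p = 7L) {
  s011 <- function(exog) sarimax_spec(0, 0, 0, 0, 1, 1, 7, exog_names = exog)
  s110 <- function(exog) sarimax_spec(0, 0, 0, 1, 1, 0, 7, exog_names = exog)
  rows <- list(
    list("long_term", "sarimax", s011(character()), character()),
    list("long_term", "sarimax", s011("holidays"), "holidays"),
    list("long_term", "var", NULL, "holidays"),
    list("two_week", "ols", NULL, "predicted_census"),
    list("two_week", "sarimax", s110("predicted_census"), "predicted_census"),
    list("two_week", "sarimax", s110(c("holidays", "surgery_count_lag7")),
         c("holidays", "surgery_count_lag7")),
    list("same_day", "sarimax", s011("holidays"), "holidays"),
    list("same_day", "sarimax", s110("predicted_census"), "predicted_census"),
    list("same_day", "sarimax", s110("adjusted_census"), "adjusted_census"),
    list("same_day", "sarimax", s110("perfect_census"), "perfect_census"),
    list("same_day", "sarimax", s110("surgery_mean_census"),
         "surgery_mean_census")
  )
  evals <- lapply(rows, function(r) {
    run_census_model(census, counts, calendar, model = r[[2]], spec = r[[3]],
                     exog_features = r[[4]], exog_data = exog_data,
                     protocol = r[[1]], test_start = test_start,
                     test_end = test_end, var_p = var_p)
  })
  summary <- do.call(rbind, lapply(evals, function(e) {
    data.frame(time_point = e$protocol, model = e$spec,
               exog = if (length(e$exog_features))
                 paste(e$exog_features, collapse = ", ") else "none",
               rmse = e$rmse, sd = e$sd, n = e$n,
               stringsAsFactors = FALSE)
  }))
  structure(list(evals = evals, summary = summary), class = "surgecast_grid")
}

#' @export
print.surgecast_grid <- function(x, ...) {
  cat("Forecasting performance (RMSE and SD of absolute errors, beds)\n")
  s <- x$summary
  s$rmse <- sprintf("%.2f", s$rmse)
  s$sd <- sprintf("%.2f", s$sd)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Express a census forecast error relative to a capacity reference
#'
#' @param evaluation a `surgecast_eval`.
#' @param capacity_reference positive bed count used as the denominator
#'   (e.g. the maximum daily inpatient census).
#' @return list with `rmse`, `capacity_reference`, `relative_rmse_pct`
#'   (`100 * rmse / capacity_reference`) and `max_observed_census`.
#' @export
relative_error_report <- function(evaluation, capacity_reference) {
  check_nonneg(capacity_reference, "capacity_reference")
  if (capacity_reference <= 0) {
    stop("`capacity_reference` must be positive", call. = FALSE)
  }
  list(rmse = evaluation$rmse,
       capacity_reference = capacity_reference,
       relative_rmse_pct = 100 * evaluation$rmse / capacity_reference,
       max_observed_census = if (nrow(evaluation$forecasts))
         max(evaluation$forecasts$actual) else NA_real_)
}
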