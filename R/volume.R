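#' Day-indexed numeric series
#'
#' @param values numeric vector, one value per day.
#' @param calendar optional `surgecast_calendar` of the same length (attached
#'   as an attribute).
#' @param day_index integer day indices; defaults to `0:(length(values)-1)`.
#' @param name label.
#' @return an object of class `surgecast_series` (a data frame with columns
#'   `day_index`, `value`).
#' @export
daily_series <- function(values, calendar = NULL, day_index = NULL,
                         name = "series") {
  if (is.null(day_index)) day_index <- seq_along(values) - 1L
  stopifnot(length(values) == length(day_index))
  if (!is.null(calendar) && nrow(calendar) != length(values)) {
    stop("calendar length does not match the series", call. = FALSE)
  }
  s <- data.frame(day_index = as.integer(day_index), value = as.numeric(values))
  attr(s, "name") <- name
  attr(s, "calendar") <- calendar
  class(s) <- c("surgecast_series", "data.frame")
  s
}

series_values <- function(x) if (inherits(x, "surgecast_series")) x$value else as.numeric(x)

#' Daily surgical case counts
#'
#' @param encounters encounter data frame.
#' @param calendar a `surgecast_calendar`; every `day_index` must fall inside
#'   it. Days without cases count 0.
#' @return a `surgecast_series` of counts.
#' @export
build_daily_counts <- function(encounters, calendar) {
  n_days <- nrow(calendar)
  d <- encounters$day_index
  if (length(d) && (any(d < 0) || any(d >= n_days))) {
    stop("encounter day_index outside the calendar", call. = FALSE)
  }
  counts <- tabulate(d + 1L, nbins = n_days)
  daily_series(counts, calendar = calendar, name = "daily_counts")
}

#' Sample ACF and PACF with white-noise significance bands
#'
#' @param series a `surgecast_series` or numeric vector.
#' @param max_lag maximum lag (must be below the series length).
#' @return an object of class `surgecast_correlogram`: data frames `acf`
#'   (lags `0..max_lag`, column `significant` versus the +/- 1.96/sqrt(n)
#'   band, lag 0 exempt) and `pacf` (lags `1..max_lag`), plus `band` and a
#'   `degenerate` flag (constant input; correlations undefined past lag 0).
#' @export
correlogram <- function(series, max_lag = 30L) {
  x <- series_values(series)
  max_lag <- check_count(max_lag, "max_lag")
  if (max_lag >= length(x)) stop("max_lag must be below the series length",
                                 call. = FALSE)
  band <- 1.96 / sqrt(length(x))
  if (stats::sd(x) == 0) {
    acf_df <- data.frame(lag = 0:max_lag,
                         acf = c(1, rep(NA_real_, max_lag)),
                         significant = FALSE)
    pacf_df <- data.frame(lag = seq_len(max_lag), pacf = NA_real_,
                          significant = FALSE)
    return(structure(list(acf = acf_df, pacf = pacf_df, band = band,
                          degenerate = TRUE),
                     class = "surgecast_correlogram"))
  }
  a <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  p <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  acf_df <- data.frame(lag = 0:max_lag, acf = a,
                       significant = c(FALSE, abs(a[-1]) > band))
  pacf_df <- data.frame(lag = seq_len(max_lag), pacf = p,
                        significant = abs(p) > band)
  structure(list(acf = acf_df, pacf = pacf_df, band = band,
                 degenerate = FALSE),
            class = "surgecast_correlogram")
}

#' @export
print.surgecast_correlogram <- function(x, ...) {
  sig <- x$acf$lag[x$acf$significant]
  cat(sprintf("<surgecast_correlogram> band +/-%.3f; significant ACF lags: %s\n",
              x$band, if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Seasonal differencing
#'
#' `y(d) = x(d) - x(d - period)`, applied `order` times; the first
#' `period * order` days are dropped.
#'
#' @param series `surgecast_series` or numeric vector.
#' @param period seasonal period (7 for a weekly cycle).
#' @param order number of seasonal differences.
#' @return a `surgecast_series` of the differenced values (day indices keep
#'   their original labels).
#' @export
seasonal_difference <- function(series, period = 7L, order = 1L) {
  x <- series_values(series)
  period <- check_count(period, "period")
  order <- check_count(order, "order")
  if (length(x) <= period * order) {
    stop("series too short for the requested seasonal difference",
         call. = FALSE)
  }
  d <- diff(x, lag = period, differences = order)
  idx <- if (inherits(series, "surgecast_series")) {
    series$day_index[-seq_len(period * order)]
  } else {
    seq_along(d) - 1L + period * order
  }
  daily_series(d, day_index = idx, name = "seasonal_difference")
}

#' Seasonal ARIMA model specification
#'
#' Orders follow the standard (p,d,q)(P,D,Q)m notation; exogenous regressors
#' (the X of SARIMAX) are named so alignment can be audited.
#'
#' @param p,d,q nonseasonal AR, differencing and MA orders.
#' @param P,D,Q seasonal orders.
#' @param m seasonal period.
#' @param exog_names character vector naming the exogenous features.
#' @return an object of class `surgecast_sarimax_spec`.
#' @export
sarimax_spec <- function(p = 0L, d = 0L, q = 0L, P = 0L, D = 1L, Q = 1L,
                         m = 7L, exog_names = character()) {
  ords <- c(p = p, d = d, q = q, P = P, D = D, Q = Q)
  if (any(ords < 0) || any(ords != floor(ords))) {
    stop("all orders must be nonnegative integers", call. = FALSE)
  }
  structure(list(order = c(p, d, q), seasonal = c(P, D, Q),
                 m = check_count(m, "m"),
                 exog_names = as.character(exog_names)),
            class = "surgecast_sarimax_spec")
}

#' @export
format.surgecast_sarimax_spec <- function(x, ...) {
  base <- sprintf("SARIMA%s(%s)(%s)%d",
                  if (length(x$exog_names)) "X" else "",
                  paste(x$order, collapse = ","),
                  paste(x$seasonal, collapse = ","), x$m)
  if (length(x$exog_names)) {
    paste0(base, " + ", paste(x$exog_names, collapse = ", "))
  } else {
    base
  }
}

#' @export
print.surgecast_sarimax_spec <- function(x, ...) {
  cat("<surgecast_sarimax_spec>", format(x), "\n")
  invisible(x)
}

#' Fit a SARIMA/SARIMAX model by state-space maximum likelihood
#'
#' A thin wrapper around [stats::arima()] that carries the named exogenous
#' matrix, retries with conditional-sum-of-squares estimation when the ML fit
#' fails to converge, and raises a classed error (`surgecast_fit_error`) with
#' diagnostics otherwise.
#'
#' @param series `surgecast_series` or numeric vector.
#' @param spec a [sarimax_spec()].
#' @param xreg optional numeric matrix of exogenous regressors (rows aligned
#'   with the series, columns named as in `spec$exog_names`).
#' @return an object of class `surgecast_sarimax` with elements `fit` (the
#'   `Arima` object), `spec` and `n`.
#' @export
fit_sarimax <- function(series, spec, xreg = NULL) {
  stopifnot(inherits(spec, "surgecast_sarimax_spec"))
  y <- series_values(series)
  if (length(spec$exog_names)) {
    if (is.null(xreg)) stop("spec names exogenous features but xreg is NULL",
                            call. = FALSE)
    xreg <- as.matrix(xreg)
    if (nrow(xreg) != length(y)) {
      stop("xreg is not aligned with the series", call. = FALSE)
    }
    colnames(xreg) <- spec$exog_names
  } else {
    xreg <- NULL
  }
  # When the exogenous set explains the target exactly (zero residual
  # variance, e.g. an oracle census array identical to the target), the ARMA
  # component is unidentifiable and state-space estimation breaks down; the
  # model then reduces to the exact linear regression on the exogenous set.
  if (!is.null(xreg)) {
    lf <- stats::lm.fit(cbind(`(Intercept)` = 1, xreg), y)
    if (stats::sd(lf$residuals) < 1e-6 * (stats::sd(y) + 1)) {
      beta <- lf$coefficients
      beta[is.na(beta)] <- 0
      return(structure(list(fit = NULL, spec = spec, n = length(y),
                            residuals = unname(lf$residuals),
                            degenerate_beta = beta),
                       class = "surgecast_sarimax"))
    }
  }
  # An exactly periodic series has a zero-variance seasonal difference; the
  # likelihood is then degenerate and the model reduces to the seasonal
  # random walk (with drift equal to the mean seasonal difference).
  if (is.null(xreg) && spec$order[2] == 0L && spec$seasonal[2] == 1L &&
      length(y) > spec$m + 1L) {
    dy <- diff(y, lag = spec$m)
    if (stats::sd(dy) < 1e-8 * (stats::sd(y) + 1)) {
      return(structure(list(fit = NULL, spec = spec, n = length(y),
                            residuals = dy - mean(dy),
                            seasonal_naive = list(tail_y = y, drift = mean(dy))),
                       class = "surgecast_sarimax"))
    }
  }
  try_fit <- function(method) {
    tryCatch(
      suppressWarnings(stats::arima(
        y, order = spec$order,
        seasonal = list(order = spec$seasonal, period = spec$m),
        xreg = xreg, method = method,
        optim.control = list(maxit = 500))),
      error = function(e) e
    )
  }
  fit <- try_fit("CSS-ML")
  if (inherits(fit, "error")) fit <- try_fit("CSS")
  if (!inherits(fit, "error")) {
    # predict.Arima re-evaluates the call's xreg in the caller's frame;
    # pin the materialized matrix so forecasting works from any scope
    fit$call$xreg <- xreg
  }
  if (inherits(fit, "error")) {
    stop(structure(class = c("surgecast_fit_error", "error", "condition"),
                   list(message = sprintf("SARIMAX fit failed for %s: %s",
                                          format(spec), conditionMessage(fit)),
                        call = NULL)))
  }
  structure(list(fit = fit, spec = spec, n = length(y)),
            class = "surgecast_sarimax")
}

#' @rdname fit_sarimax
#' @param model a fitted `surgecast_sarimax`.
#' @param horizon number of steps ahead.
#' @param newxreg exogenous matrix for every forecast step (required when the
#'   spec has exogenous features).
#' @return `forecast_sarimax()` returns a numeric vector of point forecasts.
#' @export
forecast_sarimax <- function(model, horizon, newxreg = NULL) {
  stopifnot(inherits(model, "surgecast_sarimax"))
  horizon <- check_count(horizon, "horizon")
  if (length(model$spec$exog_names)) {
    if (is.null(newxreg)) {
      stop("future exogenous values required for every forecast day",
           call. = FALSE)
    }
    newxreg <- as.matrix(newxreg)
    if (nrow(newxreg) != horizon) {
      stop("newxreg must supply one row per forecast step", call. = FALSE)
    }
    colnames(newxreg) <- model$spec$exog_names
  } else {
    newxreg <- NULL
  }
  if (!is.null(model$degenerate_beta)) {
    return(as.numeric(cbind(1, newxreg) %*% model$degenerate_beta))
  }
  if (!is.null(model$seasonal_naive)) {
    m <- model$spec$m
    x <- model$seasonal_naive$tail_y
    for (s in seq_len(horizon)) {
      x <- c(x, x[length(x) - m + 1L] + model$seasonal_naive$drift)
    }
    return(x[length(model$seasonal_naive$tail_y) + seq_len(horizon)])
  }
  as.numeric(stats::predict(model$fit, n.ahead = horizon,
                            newxreg = newxreg)$pred)
}

#' Residual correlogram of a fitted SARIMAX model
#' @param model fitted `surgecast_sarimax`.
#' @param max_lag maximum lag.
#' @return a [correlogram()] of the model residuals.
#' @export
residual_correlogram <- function(model, max_lag = 30L) {
  if (is.null(model$fit)) {
    return(correlogram(model$residuals, max_lag))
  }
  correlogram(as.numeric(stats::residuals(model$fit)), max_lag)
}

#' Rolling-origin forecast evaluation
#'
#' At each origin day `t` (advancing by `step`), the model is refit on all
#' data up to and including `t` (expanding window) and days `t+1 .. t+horizon`
#' are forecast with known future exogenous values; the concatenated
#' out-of-sample forecasts are scored by RMSE. With `refit = FALSE` the
#' parameters estimated at the first origin are reused (the filter is still
#' run over the expanded data).
#'
#' @param series `surgecast_series` (target).
#' @param spec a [sarimax_spec()].
#' @param exog full-length exogenous matrix aligned with the series, or
#'   `NULL`.
#' @param origin_start first origin day index.
#' @param step origin advance in days.
#' @param horizon forecast steps per origin.
#' @param refit refit at every origin (default) or reuse first-origin
#'   parameters.
#' @return an object of class `surgecast_rolling`: `forecasts` (data frame
#'   `origin`, `target_day`, `forecast`, `actual`, `error`), `rmse`, and
#'   `failures` (origins whose fit failed, which are skipped and reported).
#' @export
rolling_forecast <- function(series, spec, exog = NULL, origin_start,
                             step = 7L, horizon = 7L, refit = TRUE) {
  stopifnot(inherits(series, "surgecast_series"))
  step <- check_count(step, "step")
  horizon <- check_count(horizon, "horizon")
  y <- series$value
  idx <- series$day_index
  n <- length(y)
  first_day <- idx[1L]
  pos_of_day <- function(d) d - first_day + 1L
  if (!is.null(exog)) {
    exog <- as.matrix(exog)
    stopifnot(nrow(exog) == n)
  }
  if (origin_start > idx[n] - horizon) stop("no valid origins", call. = FALSE)
  origins <- seq(origin_start, idx[n] - horizon, by = step)
  rows <- list()
  failures <- list()
  fixed_coef <- NULL
  for (t in origins) {
    pt <- pos_of_day(t)
    y_fit <- y[seq_len(pt)]
    x_fit <- if (is.null(exog)) NULL else exog[seq_len(pt), , drop = FALSE]
    x_new <- if (is.null(exog)) NULL else
      exog[pt + seq_len(horizon), , drop = FALSE]
    res <- tryCatch({
      m <- if (refit || is.null(fixed_coef)) {
        fit_sarimax(y_fit, spec, xreg = x_fit)
      } else {
        refilter_sarimax(y_fit, spec, x_fit, fixed_coef)
      }
      if (!refit && is.null(fixed_coef)) fixed_coef <<- stats::coef(m$fit)
      forecast_sarimax(m, horizon, newxreg = x_new)
    }, surgecast_fit_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(origin = t, message = conditionMessage(res))
      next
    }
    target <- t + seq_len(horizon)
    rows[[length(rows) + 1L]] <- data.frame(
      origin = t, target_day = target, forecast = res,
      actual = y[pos_of_day(target)])
  }
  fc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(origin = integer(), target_day = integer(),
               forecast = numeric(), actual = numeric())
  fc$error <- fc$forecast - fc$actual
  structure(list(
    forecasts = fc,
    rmse = if (nrow(fc)) rmse(fc$error) else NA_real_,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(origin = integer(), message = character())
  ), class = "surgecast_rolling")
}

# Re-run the Kalman filter over expanded data with previously estimated
# parameters held fixed (no re-estimation).
refilter_sarimax <- function(y, spec, xreg, coefs) {
  fit <- suppressWarnings(stats::arima(
    y, order = spec$order,
    seasonal = list(order = spec$seasonal, period = spec$m),
    xreg = if (is.null(xreg)) NULL else {
      x <- as.matrix(xreg); colnames(x) <- spec$exog_names; x
    },
    fixed = coefs, transform.pars = FALSE, method = "CSS-ML",
    optim.control = list(maxit = 1)))
  fit$call$xreg <- if (is.null(xreg)) NULL else {
    x <- as.matrix(xreg); colnames(x) <- spec$exog_names; x
  }
  structure(list(fit = fit, spec = spec, n = length(y)),
            class = "surgecast_sarimax")
}

#' @export
print.surgecast_rolling <- function(x, ...) {
  cat(sprintf("<surgecast_rolling> %d forecasts, RMSE %.3f (%d failed origins)\n",
              nrow(x$forecasts), x$rmse, nrow(x$failures)))
  invisible(x)
}
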