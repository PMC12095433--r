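# Plain-text interchange formats: encounters and calendars as CSV (one row
# per case; comorbidity codes semicolon-joined; missing values as empty
# cells), day-indexed series as two-column CSV, reports as JSON.

#' Write / read an encounter table as CSV
#'
#' The `comorbidity_codes` list column is serialized as a semicolon-joined
#' string; missing values become empty cells.
#'
#' @param encounters encounter data frame (list column `comorbidity_codes`).
#' @param path file path.
#' @return `write_encounters()` returns `path` invisibly; `read_encounters()`
#'   returns the encounter data frame with types restored.
#' @export
write_encounters <- function(encounters, path) {
  out <- encounters
  if (!is.null(out$comorbidity_codes)) {
    out$comorbidity_codes <- vapply(out$comorbidity_codes, function(cc) {
      if (length(cc) == 0L || all(is.na(cc))) "" else paste(cc, collapse = ";")
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_encounters
#' @export
read_encounters <- function(path) {
  enc <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(case_id = "character",
                                        patient_id = "character"),
                         na.strings = "")
  if (!is.null(enc$comorbidity_codes)) {
    raw <- enc$comorbidity_codes
    raw[is.na(raw)] <- ""
    enc$comorbidity_codes <- strsplit(raw, ";", fixed = TRUE)
  }
  if (!is.null(enc$planned_same_day_discharge)) {
    enc$planned_same_day_discharge <- as.logical(enc$planned_same_day_discharge)
  }
  enc
}

#' Write / read a calendar as CSV
#' @param calendar a `surgecast_calendar` data frame.
#' @param path file path.
#' @export
write_calendar <- function(calendar, path) {
  utils::write.csv(as.data.frame(calendar), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calendar
#' @export
read_calendar <- function(path) {
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  cal$is_weekend <- as.logical(cal$is_weekend)
  cal$is_holiday <- as.logical(cal$is_holiday)
  class(cal) <- c("surgecast_calendar", "data.frame")
  cal
}

#' Write / read a day-indexed series as CSV
#' @param series a `surgecast_series` object (see [daily_series()]).
#' @param path file path.
#' @export
write_series <- function(series, path) {
  utils::write.csv(data.frame(day_index = series$day_index,
                              value = series$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param name label for the series read back.
#' @export
read_series <- function(path, name = "series") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_series(df$value, day_index = df$day_index, name = name)
}

#' Write a report object as JSON
#' @param x list-like report.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
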