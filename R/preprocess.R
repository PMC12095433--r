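#' Chronological split specification
#'
#' Day-count partition of a contiguous calendar into training, validation and
#' test windows. The default 225/70/70 split reserves the first 225 days for
#' training, the next 70 for validation and the final 70 for testing.
#'
#' @param train_end_day first day index *not* in training (exclusive bound).
#' @param val_end_day first day index not in validation (exclusive bound).
#' @param n_days calendar length.
#' @return an object of class `surgecast_split`.
#' @export
split_spec <- function(train_end_day = 225L, val_end_day = 295L,
                       n_days = 365L) {
  train_end_day <- check_count(train_end_day, "train_end_day")
  val_end_day <- check_count(val_end_day, "val_end_day")
  n_days <- check_count(n_days, "n_days")
  if (!(0L < train_end_day && train_end_day < val_end_day &&
        val_end_day <= n_days)) {
    stop("split must satisfy 0 < train_end_day < val_end_day <= n_days",
         call. = FALSE)
  }
  structure(list(train_end_day = train_end_day, val_end_day = val_end_day,
                 n_days = n_days), class = "surgecast_split")
}

#' Remove records that cannot be analyzed
#'
#' Drops rows with a missing surgery type (the only exclusion rule) and
#' reports removals by reason.
#'
#' @param encounters encounter data frame.
#' @return list with `encounters` (filtered) and `report` (data frame with
#'   `reason`, `n_removed`).
#' @export
exclude_invalid <- function(encounters) {
  missing_type <- is.na(encounters$surgery_type)
  kept <- encounters[!missing_type, , drop = FALSE]
  if (nrow(kept) == 0L && nrow(encounters) > 0L) {
    warning("all records excluded (every surgery type missing)", call. = FALSE)
  }
  list(
    encounters = kept,
    report = data.frame(reason = "missing_surgery_type",
                        n_removed = sum(missing_type),
                        stringsAsFactors = FALSE)
  )
}

#' Split encounters chronologically by surgery day
#'
#' Membership is determined solely by `day_index`; rows are never shuffled.
#'
#' @param encounters encounter data frame.
#' @param spec a [split_spec()].
#' @return list with `train`, `val`, `test` data frames.
#' @export
chronological_split <- function(encounters, spec) {
  stopifnot(inherits(spec, "surgecast_split"))
  d <- encounters$day_index
  if (length(d) && max(d) >= spec$n_days) {
    stop("encounter day_index exceeds the split calendar", call. = FALSE)
  }
  list(
    train = encounters[d < spec$train_end_day, , drop = FALSE],
    val = encounters[d >= spec$train_end_day & d < spec$val_end_day, ,
                     drop = FALSE],
    test = encounters[d >= spec$val_end_day, , drop = FALSE]
  )
}

# Deterministic mode with ties broken toward the smallest value.
mode_smallest <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which(tab == max(tab))[1L]])
}

#' Fit per-surgery-type imputation statistics on a fitting window
#'
#' Missing scheduled durations and LOS values are imputed by the mean of the
#' same surgery type in the fitting window; missing ASA PS by the per-type
#' mode (ties broken toward the smallest score). A type absent from the
#' window, or all-missing within it, falls back to the global mean for
#' numeric fields and to the `"unknown"` token for ASA PS (which remains
#' `NA` in the column and is one-hot encoded as its own category
#' downstream).
#'
#' @param train fitting-window encounter data frame (non-empty).
#' @return an object of class `surgecast_imputer`.
#' @export
fit_imputer <- function(train) {
  if (nrow(train) == 0L) stop("fitting window is empty", call. = FALSE)
  by_type <- split(train, train$surgery_type)
  stats_tbl <- data.frame(
    surgery_type = names(by_type),
    mean_duration = vapply(by_type, function(d)
      mean(d$scheduled_duration_min, na.rm = TRUE), numeric(1)),
    mean_los = vapply(by_type, function(d)
      mean(d$los_days, na.rm = TRUE), numeric(1)),
    asa_mode = vapply(by_type, function(d)
      mode_smallest(d$asa_ps), integer(1)),
    stringsAsFactors = FALSE
  )
  stats_tbl$mean_duration[is.nan(stats_tbl$mean_duration)] <- NA_real_
  stats_tbl$mean_los[is.nan(stats_tbl$mean_los)] <- NA_real_
  structure(list(
    per_type = stats_tbl,
    global_mean_duration = mean(train$scheduled_duration_min, na.rm = TRUE),
    global_mean_los = mean(train$los_days, na.rm = TRUE),
    unknown_token = "unknown"
  ), class = "surgecast_imputer")
}

#' @rdname fit_imputer
#' @param model a fitted `surgecast_imputer`.
#' @param table encounter data frame to impute; the operation is idempotent.
#' @return `apply_imputer()` returns the imputed table.
#' @export
apply_imputer <- function(model, table) {
  stopifnot(inherits(model, "surgecast_imputer"))
  idx <- match(table$surgery_type, model$per_type$surgery_type)
  fill <- function(col, per_type, global) {
    miss <- is.na(col)
    if (!any(miss)) return(col)
    v <- per_type[idx[miss]]
    v[is.na(v)] <- global
    col[miss] <- v
    col
  }
  table$scheduled_duration_min <- fill(table$scheduled_duration_min,
                                       model$per_type$mean_duration,
                                       model$global_mean_duration)
  table$los_days <- fill(table$los_days, model$per_type$mean_los,
                         model$global_mean_los)
  miss_asa <- is.na(table$asa_ps)
  if (any(miss_asa)) {
    v <- model$per_type$asa_mode[idx[miss_asa]]
    # types unseen or all-missing keep NA, i.e. the "unknown" category
    table$asa_ps[miss_asa] <- v
  }
  table
}

#' Select the most frequent comorbidity codes in a fitting window
#'
#' Codes are ranked by the number of cases carrying them, frequency
#' descending with lexicographic tie-break. Later encoding restricts
#' validation/test cases to this vocabulary.
#'
#' @param train fitting-window encounter data frame.
#' @param n vocabulary size.
#' @return character vector of codes (length `min(n, distinct codes)`; a
#'   warning is emitted when fewer than `n` codes exist).
#' @export
select_top_n_codes <- function(train, n) {
  n <- check_count(n, "n")
  codes <- unlist(train$comorbidity_codes, use.names = FALSE)
  codes <- codes[!is.na(codes)]
  tab <- table(codes)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  vocab <- names(tab)[ord]
  if (length(vocab) < n) {
    warning(sprintf("only %d distinct codes in fitting window (requested %d)",
                    length(vocab), n), call. = FALSE)
    return(vocab)
  }
  vocab[seq_len(n)]
}

#' Build the sparse case-by-code incidence matrix
#'
#' @param table encounter data frame.
#' @param vocabulary ordered code vocabulary (columns); codes outside it are
#'   ignored.
#' @return a sparse binary `Matrix::dgCMatrix` with case ids as row names and
#'   the vocabulary as column names.
#' @export
build_onehot_matrix <- function(table, vocabulary) {
  if (length(vocabulary) == 0L) stop("vocabulary is empty", call. = FALSE)
  n <- nrow(table)
  code_list <- table$comorbidity_codes
  lens <- lengths(code_list)
  i <- rep.int(seq_len(n), lens)
  j <- match(unlist(code_list, use.names = FALSE), vocabulary)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(n, length(vocabulary)),
                            dimnames = list(table$case_id, vocabulary))
  # a case may be recorded with the same code twice upstream; clamp to binary
  m@x[] <- 1
  m
}

#' Fraction of zero entries in an incidence matrix
#' @param matrix a sparse incidence matrix.
#' @return scalar in `[0, 1]`.
#' @export
sparsity <- function(matrix) {
  1 - Matrix::nnzero(matrix) / prod(dim(matrix))
}
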