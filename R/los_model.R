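#' Random-forest hyperparameters for the LOS model
#'
#' Defaults follow the tuned configuration for this task: each tree sees at
#' most 92% of the training rows and grows to at most 580 leaves. The number
#' of trees defaults to 500.
#'
#' @param n_trees number of trees.
#' @param max_leaf_nodes maximum terminal nodes per tree.
#' @param max_samples_fraction fraction of training rows drawn (without
#'   replacement) for each tree, in `(0, 1]`.
#' @param max_depth optional depth cap, honored by additionally capping
#'   leaves at `2^max_depth`.
#' @param min_samples_split minimum samples to split a node (mapped to the
#'   forest's minimum terminal-node size, `ceiling(min_samples_split / 2)`).
#' @param mtry features tried per split; default `floor(p / 3)` as usual for
#'   regression forests.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return an object of class `surgecast_forest_spec`.
#' @export
forest_spec <- function(n_trees = 500L, max_leaf_nodes = 580L,
                        max_samples_fraction = 0.92, max_depth = NULL,
                        min_samples_split = 2L, mtry = NULL, seed = 1L) {
  n_trees <- check_count(n_trees, "n_trees")
  max_leaf_nodes <- check_count(max_leaf_nodes, "max_leaf_nodes", min = 2L)
  if (!is.numeric(max_samples_fraction) || max_samples_fraction <= 0 ||
      max_samples_fraction > 1) {
    stop("`max_samples_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(n_trees = n_trees, max_leaf_nodes = max_leaf_nodes,
                 max_samples_fraction = max_samples_fraction,
                 max_depth = max_depth,
                 min_samples_split = check_count(min_samples_split,
                                                 "min_samples_split", min = 2L),
                 mtry = mtry, seed = check_count(seed, "seed", min = 0L)),
            class = "surgecast_forest_spec")
}

#' Historic mean LOS per surgery type
#'
#' The engineered feature: the average observed LOS of each surgery type over
#' the fitting window only. Types unseen at prediction time fall back to the
#' window's global mean.
#'
#' @param fitting_window non-empty encounter data frame.
#' @return list with `type_means` (named numeric) and `global` (scalar).
#' @export
compute_historic_mean_los <- function(fitting_window) {
  if (nrow(fitting_window) == 0L) stop("fitting window is empty", call. = FALSE)
  means <- tapply(fitting_window$los_days, fitting_window$surgery_type,
                  mean, na.rm = TRUE)
  list(type_means = unlist(as.list(means)),
       global = mean(fitting_window$los_days, na.rm = TRUE))
}

#' Feature schema for the LOS model
#'
#' Freezes the category levels observed in the training window so that
#' validation/test encoding is fixed: unseen categories map to an all-zero
#' one-hot block. Numeric features are age, scheduled duration, comorbidity
#' count, historic mean LOS for the surgery type, ASA PS (ordinal, with a
#' separate indicator for the "unknown" category) and the `k` decomposition
#' scores; sex, service line and planned admission class are one-hot encoded.
#'
#' @param train training encounter data frame.
#' @param k number of decomposition score columns.
#' @param score_prefix column-name prefix of the score block (e.g. `"svd"`).
#' @return an object of class `surgecast_los_schema`.
#' @export
los_schema <- function(train, k, score_prefix = "svd") {
  k <- check_count(k, "k")
  structure(list(
    k = k,
    score_cols = sprintf("%s_%02d", score_prefix, seq_len(k)),
    sex_levels = sort(unique(train$sex)),
    service_levels = sort(unique(train$service_line)),
    class_levels = sort(unique(train$planned_admission_class))
  ), class = "surgecast_los_schema")
}

onehot_block <- function(x, levels, prefix) {
  m <- matrix(0, nrow = length(x), ncol = length(levels),
              dimnames = list(NULL, paste0(prefix, "_", levels)))
  j <- match(x, levels)
  ok <- !is.na(j)
  m[cbind(which(ok), j[ok])] <- 1
  m
}

#' Assemble the LOS feature matrix and target vector
#'
#' @param table imputed encounter data frame.
#' @param scores decomposition score matrix for the same rows (columns named
#'   per the schema's score prefix).
#' @param historic output of [compute_historic_mean_los()].
#' @param schema a [los_schema()] fitted on the training window.
#' @return list with `X` (numeric matrix, one row per case, fixed column
#'   layout), `y` (LOS days) and `feature_names`.
#' @export
assemble_los_features <- function(table, scores, historic, schema) {
  stopifnot(inherits(schema, "surgecast_los_schema"))
  if (!identical(colnames(scores), schema$score_cols)) {
    stop("decomposition scores do not match the feature schema", call. = FALSE)
  }
  if (nrow(scores) != nrow(table)) {
    stop("scores and table have different numbers of cases", call. = FALSE)
  }
  hist_los <- historic$type_means[table$surgery_type]
  hist_los[is.na(hist_los)] <- historic$global
  asa_unknown <- as.numeric(is.na(table$asa_ps))
  asa_value <- ifelse(is.na(table$asa_ps), 0, table$asa_ps)
  X <- cbind(
    age_years = table$age_years,
    scheduled_duration_min = table$scheduled_duration_min,
    n_comorbidities = table$n_comorbidities,
    historic_mean_los = unname(hist_los),
    asa_ps = asa_value,
    asa_unknown = asa_unknown,
    scores,
    onehot_block(table$sex, schema$sex_levels, "sex"),
    onehot_block(table$service_line, schema$service_levels, "service"),
    onehot_block(table$planned_admission_class, schema$class_levels, "admit")
  )
  rownames(X) <- table$case_id
  list(X = X, y = table$los_days, feature_names = colnames(X))
}

#' Fit the LOS random forest / predict per-case LOS
#'
#' @param X numeric feature matrix (finite values).
#' @param y nonnegative LOS targets.
#' @param spec a [forest_spec()].
#' @return `fit_los_forest()` returns an object of class
#'   `surgecast_los_forest`; `predict_los()` returns nonnegative predicted
#'   LOS in days (invariant to row order).
#' @export
fit_los_forest <- function(X, y, spec = forest_spec()) {
  stopifnot(inherits(spec, "surgecast_forest_spec"))
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (any(y < 0)) stop("LOS targets must be nonnegative", call. = FALSE)
  maxnodes <- spec$max_leaf_nodes
  if (!is.null(spec$max_depth)) {
    maxnodes <- min(maxnodes, 2^spec$max_depth)
  }
  sampsize <- max(1L, floor(spec$max_samples_fraction * nrow(X)))
  # a tree grown on s rows cannot carry more than s leaves
  maxnodes <- min(maxnodes, sampsize)
  mtry <- spec$mtry %||% max(1L, floor(ncol(X) / 3))
  fit <- with_seed(spec$seed,
    randomForest::randomForest(
      x = X, y = y, ntree = spec$n_trees, maxnodes = maxnodes,
      sampsize = sampsize, replace = FALSE, mtry = mtry,
      nodesize = max(1L, ceiling(spec$min_samples_split / 2))
    ))
  structure(list(forest = fit, spec = spec, feature_names = colnames(X)),
            class = "surgecast_los_forest")
}

#' @rdname fit_los_forest
#' @param model a fitted `surgecast_los_forest`.
#' @export
predict_los <- function(model, X) {
  stopifnot(inherits(model, "surgecast_los_forest"))
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  pmax(0, as.numeric(stats::predict(model$forest, X)))
}

#' Per-type mean-LOS baseline predictions
#'
#' The comparison model: every case of a surgery type is predicted at that
#' type's historic mean LOS.
#'
#' @param historic output of [compute_historic_mean_los()].
#' @param surgery_type character vector of types to predict for.
#' @return numeric predictions.
#' @export
predict_mean_los_baseline <- function(historic, surgery_type) {
  p <- historic$type_means[surgery_type]
  p[is.na(p)] <- historic$global
  unname(p)
}

#' Evaluate LOS predictions
#'
#' @param predicted,observed numeric vectors of equal, nonzero length.
#' @param strata_cutoff LOS threshold (days) splitting the short-stay stratum
#'   from the long-stay stratum in the stratified error report.
#' @return an object of class `surgecast_los_eval` with `rmse`, `mae` and a
#'   `strata` data frame.
#' @export
evaluate_los <- function(predicted, observed, strata_cutoff = 10) {
  stopifnot(length(predicted) == length(observed), length(observed) > 0L)
  err <- predicted - observed
  strat <- function(mask, label) {
    if (!any(mask)) {
      return(data.frame(stratum = label, n = 0L, rmse = NA_real_,
                        mae = NA_real_))
    }
    data.frame(stratum = label, n = sum(mask), rmse = rmse(err[mask]),
               mae = mean(abs(err[mask])))
  }
  structure(list(
    rmse = rmse(err),
    mae = mean(abs(err)),
    strata = rbind(
      strat(observed < strata_cutoff, sprintf("los_lt_%g", strata_cutoff)),
      strat(observed >= strata_cutoff, sprintf("los_ge_%g", strata_cutoff))
    )
  ), class = "surgecast_los_eval")
}

#' @export
print.surgecast_los_eval <- function(x, ...) {
  cat(sprintf("<surgecast_los_eval> RMSE %.3f days, MAE %.3f days\n",
              x$rmse, x$mae))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Permutation importance of LOS features
#'
#' For each feature, the increase in evaluation MSE when that column is
#' randomly shuffled, averaged over `n_repeats` permutations; features are
#' returned ranked by decreasing importance.
#'
#' @param model fitted `surgecast_los_forest`.
#' @param X,y evaluation features and targets.
#' @param n_repeats number of shuffles per feature.
#' @param seed integer seed.
#' @return data frame with `feature`, `importance` (mean MSE increase),
#'   `sd` and `rank`.
#' @export
los_permutation_importance <- function(model, X, y, n_repeats = 10L,
                                       seed = 1L) {
  n_repeats <- check_count(n_repeats, "n_repeats")
  base_mse <- mean((predict_los(model, X) - y)^2)
  with_seed(seed, {
    imp <- sapply(seq_len(ncol(X)), function(j) {
      deltas <- replicate(n_repeats, {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        mean((predict_los(model, Xp) - y)^2) - base_mse
      })
      c(mean(deltas), stats::sd(deltas))
    })
    out <- data.frame(feature = colnames(X), importance = imp[1, ],
                      sd = imp[2, ], stringsAsFactors = FALSE)
    out <- out[order(-out$importance), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}
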