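toy_table <- function() {
  data.frame(
    case_id = sprintf("C%d", 1:5),
    day_index = c(0L, 1L, 2L, 3L, 4L),
    surgery_type = c("A", "A", "A", "B", "B"),
    scheduled_duration_min = c(30, 60, NA, 100, NA),
    los_days = c(1, 3, NA, 2, NA),
    asa_ps = c(2L, 2L, 3L, NA, NA),
    stringsAsFactors = FALSE
  )
}

test_that("records with a missing surgery type are excluded and reported", {
  enc <- data.frame(surgery_type = c("A", "B"), day_index = 0:1)
  out <- exclude_invalid(enc)
  expect_identical(out$encounters, enc)
  expect_equal(out$report$n_removed, 0L)

  enc2 <- rbind(enc, data.frame(surgery_type = NA, day_index = 2L))
  out2 <- exclude_invalid(enc2)
  expect_equal(nrow(out2$encounters), 2L)
  expect_equal(out2$report$n_removed, 1L)

  enc3 <- data.frame(surgery_type = c(NA, NA), day_index = 0:1)
  expect_warning(out3 <- exclude_invalid(enc3), "all records excluded")
  expect_equal(nrow(out3$encounters), 0L)
})

test_that("chronological split partitions rows by day index alone", {
  spec <- split_spec(225, 295, 365)
  expect_error(split_spec(295, 225, 365), "train_end_day < val_end_day")

  sim <- generate_encounters(tiny_gen_config(1, n_days = 365L))
  sp <- chronological_split(sim$encounters, spec)
  expect_true(all(sp$train$day_index < 225))
  expect_true(all(sp$val$day_index >= 225 & sp$val$day_index < 295))
  expect_true(all(sp$test$day_index >= 295))
  # partition law: union is the input, pieces are disjoint
  recombined <- rbind(sp$train, sp$val, sp$test)
  expect_equal(nrow(recombined), nrow(sim$encounters))
  expect_setequal(recombined$case_id, sim$encounters$case_id)
  expect_equal(anyDuplicated(recombined$case_id), 0L)

  tiny <- data.frame(surgery_type = "A", day_index = 0:2)
  sp3 <- chronological_split(tiny, split_spec(1, 2, 3))
  expect_equal(sapply(sp3, nrow), c(train = 1L, val = 1L, test = 1L))

  expect_error(chronological_split(data.frame(day_index = 10L),
                                   split_spec(1, 2, 3)),
               "exceeds the split calendar")
})

test_that("imputation follows the per-type mean/mode rules with unknown fallback", {
  toy <- toy_table()
  imp <- fit_imputer(toy)
  out <- apply_imputer(imp, toy)

  expect_equal(out$scheduled_duration_min[3], 45)   # mean of 30, 60
  expect_equal(out$los_days[3], 2)                  # mean of 1, 3
  expect_equal(out$asa_ps[3], 3L)                   # was present, untouched
  expect_equal(out$los_days[5], 2)                  # type B mean
  expect_equal(out$scheduled_duration_min[5], 100)

  # ASA mode with tie broken toward the smallest value
  tie <- data.frame(surgery_type = "T", scheduled_duration_min = 1,
                    los_days = 1, asa_ps = c(2L, 2L, 3L, 3L, NA))
  out_tie <- apply_imputer(fit_imputer(tie), tie)
  expect_equal(out_tie$asa_ps[5], 2L)

  # type with every ASA missing keeps the unknown (NA) category
  unk <- data.frame(surgery_type = "U", scheduled_duration_min = 5,
                    los_days = 1, asa_ps = NA_integer_)
  expect_true(is.na(apply_imputer(fit_imputer(unk), unk)$asa_ps))

  # type unseen in the fitting window falls back to the global mean
  new_type <- data.frame(surgery_type = "Z", scheduled_duration_min = NA,
                         los_days = NA, asa_ps = NA_integer_)
  out_new <- apply_imputer(imp, new_type)
  expect_equal(out_new$scheduled_duration_min,
               mean(toy$scheduled_duration_min, na.rm = TRUE))
  expect_equal(out_new$los_days, mean(toy$los_days, na.rm = TRUE))

  # idempotence
  expect_identical(apply_imputer(imp, out), out)
  expect_error(fit_imputer(toy[0, ]), "empty")
})

test_that("top-n code selection orders by frequency with lexicographic ties", {
  tbl <- data.frame(surgery_type = "A")
  tbl <- tbl[rep(1, 9), , drop = FALSE]
  tbl$comorbidity_codes <- list(
    c("x", "y"), c("x", "z"), c("x"), c("x", "y"), c("x"),
    c("y"), c("y"), c("z"), c("w")
  )
  # frequencies: x 5, y 4, z 2, w 1
  expect_equal(select_top_n_codes(tbl, 2), c("x", "y"))
  expect_equal(select_top_n_codes(tbl, 4), c("x", "y", "z", "w"))
  expect_warning(v <- select_top_n_codes(tbl, 10), "only 4 distinct")
  expect_equal(length(v), 4L)

  tie <- data.frame(surgery_type = "A")[rep(1, 2), , drop = FALSE]
  tie$comorbidity_codes <- list(c("b"), c("a"))
  expect_equal(select_top_n_codes(tie, 1), "a")
})

test_that("one-hot incidence matrix is binary, sparse and vocabulary-restricted", {
  tbl <- data.frame(case_id = c("c1", "c2", "c3"))
  tbl$comorbidity_codes <- list(c("a", "b"), c("d"), character())
  m <- build_onehot_matrix(tbl, c("a", "c"))
  expect_s4_class(m, "dgCMatrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(as.numeric(m["c1", ]), c(1, 0))
  expect_equal(as.numeric(m["c2", ]), c(0, 0))  # off-vocabulary code ignored
  expect_equal(as.numeric(m["c3", ]), c(0, 0))

  dup <- data.frame(case_id = "c1")
  dup$comorbidity_codes <- list(c("a", "a"))
  expect_equal(max(build_onehot_matrix(dup, "a")), 1)

  expect_error(build_onehot_matrix(tbl, character()), "empty")
})

test_that("default synthetic comorbidity matrix is overwhelmingly sparse", {
  sim <- generate_encounters(test_gen_config(1))
  vocab <- select_top_n_codes(sim$encounters, 150)
  m <- build_onehot_matrix(sim$encounters, vocab)
  expect_gte(sparsity(m), 0.95)
})

test_that("truncated SVD matches a dense SVD oracle", {
  set.seed(42)
  X <- Matrix::Matrix(matrix(rbinom(50 * 20, 1, 0.3), 50, 20,
                             dimnames = list(NULL, sprintf("c%02d", 1:20))),
                      sparse = TRUE)
  X <- methods::as(X, "CsparseMatrix")
  dec <- fit_decomposition(X, "truncated_svd", k = 5)
  oracle <- svd(as.matrix(X))
  expect_equal(dec$singular_values, oracle$d[1:5], tolerance = 1e-8)
  scores <- predict(dec, X)
  expect_equal(dim(scores), c(50L, 5L))
  # scores agree with the dense oracle up to component sign
  oracle_scores <- oracle$u[, 1:5] %*% diag(oracle$d[1:5])
  expect_equal(abs(scores), abs(oracle_scores), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("rank-1 matrices are reconstructed exactly at k = 1", {
  row_pattern <- c(1, 0, 1, 1, 0)
  X <- Matrix::Matrix(outer(rep(1, 10), row_pattern), sparse = TRUE,
                      dimnames = list(NULL, sprintf("c%d", 1:5)))
  X <- methods::as(X, "CsparseMatrix")
  dec <- fit_decomposition(X, "truncated_svd", 1)
  scores <- predict(dec, X)
  recon <- scores %*% t(dec$loadings)
  expect_equal(max(abs(recon - as.matrix(X))), 0, tolerance = 1e-10)
  expect_error(fit_decomposition(X, "truncated_svd", 6), "exceeds")
})

test_that("sparse PCA path equals the dense prcomp oracle", {
  set.seed(7)
  X <- Matrix::Matrix(matrix(rbinom(40 * 12, 1, 0.4), 40, 12,
                             dimnames = list(NULL, sprintf("c%02d", 1:12))),
                      sparse = TRUE)
  X <- methods::as(X, "CsparseMatrix")
  dec <- fit_decomposition(X, "pca", 4)
  scores <- predict(dec, X)
  oracle <- stats::prcomp(as.matrix(X), center = TRUE, scale. = FALSE)
  expect_equal(abs(scores), abs(oracle$x[, 1:4]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("feature agglomeration merges duplicate columns and pools means", {
  set.seed(11)
  base <- matrix(rbinom(30 * 3, 1, 0.5), 30, 3)
  X <- Matrix::Matrix(cbind(base, base)[, c(1, 4, 2, 5, 3, 6)], sparse = TRUE,
                      dimnames = list(NULL, sprintf("c%d", 1:6)))
  X <- methods::as(X, "CsparseMatrix")
  dec <- fit_decomposition(X, "feature_agglomeration", 3)
  # identical columns must land in the same cluster
  expect_equal(unname(dec$clusters[1]), unname(dec$clusters[2]))
  expect_equal(unname(dec$clusters[3]), unname(dec$clusters[4]))
  scores <- predict(dec, X)
  expect_equal(ncol(scores), 3L)
  # mean pooling of two identical columns reproduces the column
  expect_equal(sort(unique(as.numeric(scores))), c(0, 1))
})

test_that("vocabulary and component tuning selects the informative grid point", {
  sim <- generate_encounters(tiny_gen_config(8))
  sp <- chronological_split(sim$encounters, split_spec(80, 115, 150))
  imp <- fit_imputer(sp$train)
  tr <- apply_imputer(imp, sp$train)
  va <- apply_imputer(imp, sp$val)

  single <- tune_n_and_k(tr, va, n_grid = 40, k_grid = 4,
                         methods = "truncated_svd",
                         forest = forest_spec(n_trees = 20, seed = 1))
  expect_equal(nrow(single$report), 1L)
  expect_equal(single$best$n, 40)
  expect_equal(single$best$k, 4)

  # signal concentrated in the top codes: the larger vocabulary should win
  both <- tune_n_and_k(tr, va, n_grid = c(5, 40), k_grid = 4,
                       methods = "truncated_svd",
                       forest = forest_spec(n_trees = 20, seed = 1))
  expect_gte(both$best$n, 20)
})
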