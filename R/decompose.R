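#' Fit a dimensionality reduction of the comorbidity matrix
#'
#' Three methods are supported, all fitted without densifying the sparse
#' incidence matrix:
#' \describe{
#'   \item{`truncated_svd`}{uncentered truncated SVD via the eigendecomposition
#'     of the (code-by-code) Gram matrix; scores are `X V_k`.}
#'   \item{`pca`}{mean-centered principal components computed from the Gram
#'     matrix and the column means, so centering never materializes a dense
#'     case-by-code matrix.}
#'   \item{`feature_agglomeration`}{columns merged by average-linkage
#'     hierarchical clustering on cosine distance; each component is the mean
#'     of its member columns.}
#' }
#'
#' @param matrix sparse binary case-by-code matrix (see
#'   [build_onehot_matrix()]).
#' @param method one of `"truncated_svd"`, `"pca"`, `"feature_agglomeration"`.
#' @param k number of components; must not exceed either matrix dimension.
#' @return an object of class `surgecast_decomp`; obtain scores with
#'   [predict()][predict.surgecast_decomp], giving a case-by-`k` matrix.
#' @export
fit_decomposition <- function(matrix,
                              method = c("truncated_svd", "pca",
                                         "feature_agglomeration"),
                              k) {
  method <- match.arg(method)
  k <- check_count(k, "k")
  if (k > min(dim(matrix))) {
    stop(sprintf("k = %d exceeds matrix dimensions %d x %d",
                 k, nrow(matrix), ncol(matrix)), call. = FALSE)
  }
  vocab <- colnames(matrix)
  n <- nrow(matrix)
  gram <- as.matrix(Matrix::crossprod(matrix))

  if (method == "truncated_svd") {
    eig <- eigen(gram, symmetric = TRUE)
    V <- fix_signs(eig$vectors[, seq_len(k), drop = FALSE])
    out <- list(method = method, k = k, vocabulary = vocab, loadings = V,
                singular_values = sqrt(pmax(eig$values[seq_len(k)], 0)),
                prefix = "svd")
  } else if (method == "pca") {
    mu <- Matrix::colMeans(matrix)
    cov <- (gram - n * tcrossprod(mu)) / (n - 1)
    eig <- eigen(cov, symmetric = TRUE)
    V <- fix_signs(eig$vectors[, seq_len(k), drop = FALSE])
    out <- list(method = method, k = k, vocabulary = vocab, loadings = V,
                center = mu, eigenvalues = pmax(eig$values[seq_len(k)], 0),
                prefix = "pc")
  } else {
    norms <- sqrt(pmax(diag(gram), 1e-12))
    cos_sim <- gram / outer(norms, norms)
    d <- stats::as.dist(1 - pmin(cos_sim, 1))
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
    # membership matrix with mean pooling per cluster
    sizes <- tabulate(cl, nbins = k)
    M <- Matrix::sparseMatrix(i = seq_along(cl), j = cl,
                              x = 1 / sizes[cl],
                              dims = c(length(cl), k))
    out <- list(method = method, k = k, vocabulary = vocab, pooling = M,
                clusters = cl, prefix = "agg")
  }
  structure(out, class = "surgecast_decomp")
}

# Deterministic eigenvector orientation: the largest-magnitude loading of
# each component is made positive.
fix_signs <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, `*`)
}

#' Project cases onto fitted components
#'
#' @param object a `surgecast_decomp` model.
#' @param matrix sparse incidence matrix with the model's vocabulary as
#'   columns.
#' @param ... unused.
#' @return dense numeric matrix of component scores (cases by `k`), columns
#'   named `svd_01`, `pc_01` or `agg_01` etc. according to the method.
#' @export
predict.surgecast_decomp <- function(object, matrix, ...) {
  if (!identical(colnames(matrix), object$vocabulary)) {
    stop("matrix columns do not match the fitted vocabulary", call. = FALSE)
  }
  scores <- if (object$method == "feature_agglomeration") {
    as.matrix(matrix %*% object$pooling)
  } else if (object$method == "pca") {
    sweep(as.matrix(matrix %*% object$loadings), 2,
          drop(crossprod(object$center, object$loadings)), `-`)
  } else {
    as.matrix(matrix %*% object$loadings)
  }
  colnames(scores) <- sprintf("%s_%02d", object$prefix, seq_len(object$k))
  rownames(scores) <- rownames(matrix)
  scores
}

#' @export
print.surgecast_decomp <- function(x, ...) {
  cat(sprintf("<surgecast_decomp> %s, k = %d over %d codes\n",
              x$method, x$k, length(x$vocabulary)))
  invisible(x)
}

#' Tune the comorbidity vocabulary size and component count
#'
#' Grid search over vocabulary sizes `n`, component counts `k` and reduction
#' methods, scored by the validation mean squared error of the downstream
#' LOS forest. `mode = "sequential"` (default) first selects `n` with the
#' first method at the median `k`, then searches method-by-`k` at the chosen
#' `n`; `mode = "joint"` evaluates the full cross product.
#'
#' @param train,val imputed encounter tables.
#' @param n_grid integer vector of vocabulary sizes.
#' @param k_grid integer vector of component counts.
#' @param methods decomposition methods to compare.
#' @param forest a [forest_spec()] used for the downstream model (a small
#'   forest keeps tuning affordable).
#' @param mode `"sequential"` or `"joint"`.
#' @return list with `report` (data frame: method, n, k, val_mse) and `best`
#'   (the argmin row).
#' @export
tune_n_and_k <- function(train, val, n_grid, k_grid,
                         methods = c("truncated_svd", "pca",
                                     "feature_agglomeration"),
                         forest = forest_spec(n_trees = 60L),
                         mode = c("sequential", "joint")) {
  mode <- match.arg(mode)
  stopifnot(length(n_grid) >= 1L, length(k_grid) >= 1L, length(methods) >= 1L)
  eval_point <- function(method, n, k) {
    vocab <- suppressWarnings(select_top_n_codes(train, n))
    if (k > length(vocab)) return(NA_real_)
    m_tr <- build_onehot_matrix(train, vocab)
    m_va <- build_onehot_matrix(val, vocab)
    dec <- fit_decomposition(m_tr, method, k)
    hist_los <- compute_historic_mean_los(train)
    schema <- los_schema(train, k = k, score_prefix = dec$prefix)
    tr <- assemble_los_features(train, predict(dec, m_tr), hist_los, schema)
    va <- assemble_los_features(val, predict(dec, m_va), hist_los, schema)
    fit <- fit_los_forest(tr$X, tr$y, forest)
    mean((predict_los(fit, va$X) - va$y)^2)
  }
  rows <- list()
  if (mode == "joint") {
    for (method in methods) for (n in n_grid) for (k in k_grid) {
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, n = n, k = k,
                   val_mse = eval_point(method, n, k))
    }
  } else {
    k_mid <- k_grid[ceiling(length(k_grid) / 2)]
    for (n in n_grid) {
      rows[[length(rows) + 1L]] <-
        data.frame(method = methods[1L], n = n, k = k_mid,
                   val_mse = eval_point(methods[1L], n, k_mid))
    }
    stage1 <- do.call(rbind, rows)
    n_best <- stage1$n[which.min(stage1$val_mse)]
    for (method in methods) for (k in k_grid) {
      if (method == methods[1L] && k == k_mid) next
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, n = n_best, k = k,
                   val_mse = eval_point(method, n_best, k))
    }
  }
  report <- do.call(rbind, rows)
  best <- report[which.min(report$val_mse), , drop = FALSE]
  list(report = report, best = best)
}
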