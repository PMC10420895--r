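# Feature extraction shared by the LDA and SVM surfaces: wavelength columns
# if present, otherwise every numeric non-metadata column.
feature_matrix <- function(data) {
  wl <- wavelength_names(data)
  cols <- if (length(wl)) wl else {
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], .meta_cols)
  }
  if (!length(cols)) {
    stop_lacto("no feature columns found", "lacto2dspec_input_error")
  }
  m <- as.matrix(data[cols])
  if ("sample_id" %in% names(data)) rownames(m) <- data$sample_id
  m
}

label_vector <- function(data, label_col = "label") {
  y <- data[[label_col]]
  if (is.null(y) || anyNA(y)) {
    stop_lacto("fitting requires a label for every sample",
               "lacto2dspec_label_error")
  }
  as.character(y)
}

#' Between- and within-class scatter matrices
#'
#' The dispersion matrices of the trace-ratio discriminant criterion:
#' `S_B = 1/N * sum_i N_i (xbar_i - xbar)(xbar_i - xbar)'` (between classes)
#' and `S_W = 1/N * sum_i sum_j (x_ij - xbar_i)(x_ij - xbar_i)'` (within
#' classes), where `N_i` counts class `i`, `xbar_i` is its mean vector and
#' `xbar` the grand mean. Both are symmetric positive semidefinite and their
#' sum is the total scatter `1/N * sum (x - xbar)(x - xbar)'`.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels, one per row.
#' @return A list with `S_B`, `S_W`, `class_means`, `grand_mean`, `counts`.
#' @export
scatter_matrices <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (any(table(y) < 1) || length(classes) < 1) {
    stop_lacto("every class must be nonempty", "lacto2dspec_input_error")
  }
  if (length(classes) < 2) {
    warn("single class: between-class scatter is identically zero")
  }
  n <- nrow(x)
  counts <- setNames(as.numeric(table(factor(y, classes))), classes)
  means <- do.call(rbind, lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE])))
  rownames(means) <- classes
  grand <- colMeans(x)
  dm <- sweep(means, 2, grand) * sqrt(counts)
  s_b <- crossprod(dm) / n
  s_w <- crossprod(x - means[y, , drop = FALSE]) / n
  list(S_B = s_b, S_W = s_w, class_means = means, grand_mean = grand,
       counts = counts)
}

#' Trace-ratio objective
#'
#' `tr(V' S_B V) / tr(V' S_W V)`, the quantity the discriminant projection
#' maximizes. Invariant to positive rescaling of `V`'s columns.
#'
#' @param v Projection matrix (features x dimensions).
#' @param s_b,s_w Scatter matrices.
#' @return The trace ratio.
#' @export
trace_ratio <- function(v, s_b, s_w) {
  sum(diag(crossprod(v, s_b %*% v))) / sum(diag(crossprod(v, s_w %*% v)))
}

#' Fit a trace-ratio linear discriminant model
#'
#' Seeks the orthonormal projection `V` (at most `C - 1` columns for `C`
#' classes) maximizing the between- over within-class trace ratio
#' `tr(V' S_B V) / tr(V' S_W V)`. This is the genuine trace-ratio problem,
#' solved by the standard fixed-point iteration: given the current ratio
#' `lambda`, `V` is refreshed to the leading eigenvectors of
#' `S_B - lambda * S_W` and `lambda` to the achieved ratio, which converges
#' monotonically to the global optimum over orthonormal projections. (The
#' one-shot eigensolve of `S_W^-1 S_B` maximizes the related ratio-trace
#' objective instead and can be beaten on the trace ratio itself.)
#'
#' The fit works in the span of the centred data, where both scatter
#' matrices live, so wide spectral matrices (1051 wavelengths, 97 samples)
#' reduce to an at-most-(N-1)-dimensional eigenproblem. `S_W` restricted to
#' that span can still be singular, hence a small ridge (default
#' `1e-6 * tr(S_W)/k`); `method = "pca"` additionally truncates the basis to
#' rank `N - C` (classical PCA-then-LDA). Column signs are fixed by making
#' each column's largest-magnitude entry positive.
#'
#' Classification is by nearest projected class centroid (Euclidean distance
#' in the discriminant subspace), deterministic with ties broken toward the
#' earlier class in A < B < C order.
#'
#' @param data A `spectra_tbl` (or any data frame with a label column and
#'   numeric features).
#' @param m Subspace dimension, at most `C - 1` (default `C - 1`).
#' @param ridge Regularization added to `S_W`; `NULL` for the default.
#' @param method `"ridge"` (default) or `"pca"`.
#' @param label_col Name of the label column.
#' @return A list of class `lda_model`.
#' @export
fit_lda <- function(data, m = NULL, ridge = NULL,
                    method = c("ridge", "pca"), label_col = "label") {
  method <- match.arg(method)
  x <- feature_matrix(data)
  y <- label_vector(data, label_col)
  classes <- sort(unique(y))
  c_n <- length(classes)
  if (c_n < 2) stop_lacto("need at least 2 classes", "lacto2dspec_input_error")
  m <- m %||% (c_n - 1)
  if (m < 1 || m > c_n - 1) {
    stop_lacto("m must lie in [1, C - 1]", "lacto2dspec_config_error")
  }

  # orthonormal basis of the centred data span; scatter matrices are zero on
  # its complement, so the reduction is exact
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  k <- sum(sv$d > max(1e-10 * sv$d[1], .Machine$double.eps))
  if (method == "pca") k <- min(k, nrow(x) - c_n)
  k <- max(k, m)
  q <- sv$v[, seq_len(k), drop = FALSE]
  z <- xc %*% q

  sc <- scatter_matrices(z, y)
  ridge <- ridge %||% (1e-6 * sum(diag(sc$S_W)) / k)
  if (ridge < 0) stop_lacto("ridge must be >= 0", "lacto2dspec_config_error")
  s_w <- sc$S_W + diag(ridge, k)
  if (rcond(s_w) < .Machine$double.eps) {
    stop_lacto("S_W + ridge*I is numerically singular; increase `ridge`",
               "lacto2dspec_numerical_error")
  }

  lambda <- 0
  v <- NULL
  for (it in seq_len(100)) {
    e <- eigen(sc$S_B - lambda * s_w, symmetric = TRUE)
    v <- e$vectors[, seq_len(m), drop = FALSE]
    lambda_new <- sum(diag(crossprod(v, sc$S_B %*% v))) /
      sum(diag(crossprod(v, s_w %*% v)))
    if (abs(lambda_new - lambda) < 1e-12 * (1 + abs(lambda_new))) break
    lambda <- lambda_new
  }

  v_full <- q %*% v
  for (j in seq_len(m)) {
    if (v_full[which.max(abs(v_full[, j])), j] < 0) {
      v_full[, j] <- -v_full[, j]
      v[, j] <- -v[, j]
    }
  }
  colnames(v_full) <- paste0("LD", seq_len(m))

  centroids <- sc$class_means %*% v
  colnames(centroids) <- colnames(v_full)
  structure(list(
    V = v_full, classes = classes, m = m, ridge = ridge, method = method,
    pca_center = mu, centroids = centroids,
    eigenvalues = e$values[seq_len(m)],
    trace_ratio = trace_ratio(v, sc$S_B, sc$S_W),
    feature_names = colnames(x), n = nrow(x), counts = sc$counts
  ), class = "lda_model")
}

project_lda <- function(object, x) {
  if (ncol(x) != nrow(object$V)) {
    stop_lacto("feature dimension does not match the model",
               "lacto2dspec_input_error")
  }
  if (!is.null(object$pca_center)) x <- sweep(x, 2, object$pca_center)
  x %*% object$V
}

#' Predict freshness classes with a discriminant model
#'
#' Projects new samples into the discriminant subspace and assigns the label
#' of the nearest projected class centroid.
#'
#' @param object An `lda_model`.
#' @param newdata A `spectra_tbl` or data frame with the model's features.
#' @param ... Unused.
#' @return A tibble with `sample_id` (when available), discriminant scores
#'   and `.pred`.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  z <- project_lda(object, x)
  d2 <- outer(rowSums(z^2), rowSums(object$centroids^2), "+") -
    2 * z %*% t(object$centroids)
  pred <- object$classes[apply(d2, 1, which.min)] # ties: first = class order
  out <- as_tibble(z)
  if (!is.null(rownames(x))) out <- bind_cols(tibble(sample_id = rownames(x)), out)
  out$.pred <- pred
  out
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("Trace-ratio LDA: %d features -> %d dims, classes %s\n",
              nrow(x$V), x$m, paste(x$classes, collapse = "/")))
  cat(sprintf("ridge %.3g (%s), achieved trace ratio %.4g\n",
              x$ridge, x$method, x$trace_ratio))
  invisible(x)
}
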