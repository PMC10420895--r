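#' SVM configuration
#'
#' Soft-margin kernel SVM settings: kernel family, penalty cost `C`, kernel
#' scale `G` (gamma), polynomial degree / offset, number of stratified
#' cross-validation folds and the fold seed. The cost here is the SVM penalty
#' and is unrelated to the class count of the discriminant equations.
#'
#' @param kernel One of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param cost Penalty C > 0.
#' @param gamma Kernel scale G > 0 where the kernel uses it; `NULL` defaults
#'   to 1/n_features at training time.
#' @param degree Polynomial degree.
#' @param coef0 Polynomial/sigmoid offset.
#' @param folds Stratified CV fold count (default 5).
#' @param seed Seed for fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear", "polynomial", "sigmoid"),
                       cost = 1, gamma = NULL, degree = 3, coef0 = 0,
                       folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop_lacto("cost must be > 0", "lacto2dspec_config_error")
  if (!is.null(gamma) && gamma <= 0 && kernel != "linear") {
    stop_lacto("gamma must be > 0 for this kernel", "lacto2dspec_config_error")
  }
  structure(list(kernel = kernel, cost = cost, gamma = gamma, degree = degree,
                 coef0 = coef0, folds = folds, seed = seed),
            class = "svm_config")
}

#' Evaluate a kernel function
#'
#' The four kernels in play: linear `x.y`; polynomial
#' `(G x.y + coef0)^degree`; RBF `exp(-G ||x - y||^2)`; sigmoid
#' `tanh(G x.y + coef0)`.
#'
#' @param config An [svm_config()].
#' @param x,y Numeric vectors of equal length.
#' @return The kernel value.
#' @export
#' @examples
#' kernel_eval(svm_config("linear"), c(1, 2), c(3, 4)) # 11
kernel_eval <- function(config, x, y) {
  stopifnot(length(x) == length(y))
  g <- config$gamma
  if (config$kernel != "linear") {
    if (is.null(g) || g <= 0) {
      stop_lacto("gamma must be set and > 0 for this kernel",
                 "lacto2dspec_config_error")
    }
  }
  switch(config$kernel,
    linear = sum(x * y),
    polynomial = (g * sum(x * y) + config$coef0)^config$degree,
    rbf = exp(-g * sum((x - y)^2)),
    sigmoid = tanh(g * sum(x * y) + config$coef0)
  )
}

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

e1071_kernel <- c(linear = "linear", polynomial = "polynomial",
                  rbf = "radial", sigmoid = "sigmoid")

#' Train a kernel SVM freshness model
#'
#' Soft-margin SVM with one-vs-one multiclass voting (the libsvm scheme, via
#' e1071). When `standardize = TRUE` the center/scale are learned on the
#' training data and frozen into the model, so validation samples are scaled
#' with calibration parameters only. Deterministic given data and config.
#'
#' @param data A `spectra_tbl` or data frame with labelled numeric features.
#' @param config An [svm_config()].
#' @param label_col Label column name.
#' @param standardize Standardize features per column before training
#'   (default `FALSE`). Absorbance-scale spectral features are already
#'   commensurate across wavelengths, and per-wavelength autoscaling inflates
#'   noise-dominated channels; the flag is provided for non-spectral feature
#'   tables. The choice is recorded in the model so prediction reuses it.
#' @return A list of class `milk_svm` with the fit, the resolved config
#'   (gamma filled in), the scaler and `support_count`.
#' @export
train_svm <- function(data, config = svm_config(), label_col = "label",
                      standardize = FALSE) {
  x <- feature_matrix(data)
  y <- label_vector(data, label_col)
  if (length(unique(y)) < 2) {
    stop_lacto("need at least 2 classes", "lacto2dspec_input_error")
  }
  if (any(!is.finite(x))) {
    stop_lacto("features must be finite", "lacto2dspec_input_error")
  }
  config$gamma <- config$gamma %||% (1 / ncol(x))
  scaler <- if (standardize) fit_scaler(x) else NULL
  xs <- apply_scaler(x, scaler)
  fit <- e1071::svm(xs, factor(y, levels = sort(unique(y))),
                    scale = FALSE, type = "C-classification",
                    kernel = e1071_kernel[[config$kernel]],
                    cost = config$cost, gamma = config$gamma,
                    degree = config$degree, coef0 = config$coef0)
  structure(list(fit = fit, config = config, scaler = scaler,
                 feature_names = colnames(x), classes = sort(unique(y)),
                 support_count = fit$tot.nSV),
            class = "milk_svm")
}

#' @export
print.milk_svm <- function(x, ...) {
  cat(sprintf("Kernel SVM (%s): C = %.4g, G = %.4g, %d support vectors\n",
              x$config$kernel, x$config$cost, x$config$gamma, x$support_count))
  invisible(x)
}

# One-vs-one decision from the stored support-vector pieces (libsvm layout):
# used to predict from JSON-serialized models; verified against the e1071
# predictor in the test suite.
ovo_predict <- function(parts, x) {
  k <- length(parts$labels)
  sv <- parts$SV
  kern <- function(u) {
    apply(sv, 1, function(s) kernel_eval(parts$config, s, u))
  }
  cs <- cumsum(c(0, parts$nSV))
  apply(x, 1, function(u) {
    kv <- kern(u)
    votes <- integer(k)
    p <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- p + 1
        si <- (cs[i] + 1):cs[i + 1]
        sj <- (cs[j] + 1):cs[j + 1]
        f <- sum(parts$coefs[si, j - 1] * kv[si]) +
          sum(parts$coefs[sj, i] * kv[sj]) - parts$rho[p]
        if (f > 0) votes[i] <- votes[i] + 1 else votes[j] <- votes[j] + 1
      }
    }
    parts$levels[parts$labels[which.max(votes)]]
  })
}

svm_parts <- function(model) {
  fit <- model$fit
  list(SV = fit$SV, coefs = fit$coefs, rho = fit$rho, nSV = fit$nSV,
       labels = fit$labels, levels = fit$levels, config = model$config)
}

#' Predict with a trained SVM model
#'
#' @param object A `milk_svm` (fitted in-session or read back from JSON).
#' @param newdata A `spectra_tbl` or data frame/matrix of features.
#' @param ... Unused.
#' @return A tibble with `sample_id` (when available) and `.pred`.
#' @export
predict.milk_svm <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(x) != length(object$feature_names)) {
    stop_lacto("feature dimension does not match the model",
               "lacto2dspec_input_error")
  }
  xs <- apply_scaler(x, object$scaler)
  pred <- if (!is.null(object$fit)) {
    as.character(predict(object$fit, xs))
  } else {
    unname(ovo_predict(object$parts, xs))
  }
  out <- tibble(.pred = pred)
  if (!is.null(rownames(x))) out <- bind_cols(tibble(sample_id = rownames(x)), out)
  out[rev(seq_along(out))]
}

#' Stratified k-fold cross-validated accuracy
#'
#' Samples are assigned to folds class by class under `config$seed`, the SVM
#' is refit on each training portion (standardization re-learned per fold, so
#' no information leaks from held-out samples) and the pooled accuracy over
#' all held-out predictions is returned as a fraction. Deterministic for a
#' fixed seed.
#'
#' @inheritParams train_svm
#' @return Accuracy fraction in `[0, 1]`.
#' @export
cross_val_accuracy <- function(data, config = svm_config(),
                               label_col = "label", standardize = FALSE) {
  x <- feature_matrix(data)
  y <- label_vector(data, label_col)
  k <- config$folds
  if (any(table(y) < k)) {
    stop_lacto("every class needs at least `folds` members",
               "lacto2dspec_cv_error")
  }
  fold <- integer(length(y))
  withr::with_seed(config$seed, {
    for (cl in sort(unique(y))) {
      members <- which(y == cl)
      fold[members] <- rep_len(seq_len(k), length(members))[sample.int(length(members))]
    }
  })
  correct <- 0
  df <- as_tibble(as.data.frame(x, check.names = FALSE))
  df$label <- y
  for (f in seq_len(k)) {
    model <- train_svm(df[fold != f, ], config, standardize = standardize)
    pred <- predict(model, x[fold == f, , drop = FALSE])$.pred
    correct <- correct + sum(pred == y[fold == f])
  }
  correct / length(y)
}

#' Coarse grid search over [C, G]
#'
#' Exhaustive cross-validated evaluation over a log2 grid of cost and gamma.
#' Returns the full accuracy surface (for contour plots) and the best point,
#' with ties broken toward smaller C then smaller G.
#'
#' @inheritParams train_svm
#' @param log2_cost,log2_gamma Numeric vectors of log2 grid coordinates
#'   (defaults: cost -5..15 step 2, gamma -15..3 step 2).
#' @return A list of class `grid_search`: `best` (one-row tibble), `surface`,
#'   `config` (best settings).
#' @export
grid_search <- function(data, config = svm_config(),
                        log2_cost = seq(-5, 15, by = 2),
                        log2_gamma = seq(-15, 3, by = 2),
                        label_col = "label", standardize = FALSE) {
  if (!length(log2_cost) || !length(log2_gamma)) {
    stop_lacto("empty grid", "lacto2dspec_config_error")
  }
  surface <- tidyr::expand_grid(log2_cost = log2_cost, log2_gamma = log2_gamma)
  surface$accuracy <- purrr::pmap_dbl(surface, function(log2_cost, log2_gamma) {
    cfg <- config
    cfg$cost <- 2^log2_cost
    cfg$gamma <- 2^log2_gamma
    cross_val_accuracy(data, cfg, label_col, standardize)
  })
  best <- surface |>
    arrange(desc(.data$accuracy), .data$log2_cost, .data$log2_gamma) |>
    slice(1)
  cfg <- config
  cfg$cost <- 2^best$log2_cost
  cfg$gamma <- 2^best$log2_gamma
  structure(list(best = best, surface = surface, config = cfg),
            class = "grid_search")
}

#' Particle swarm optimizer configuration
#'
#' @param swarm Number of particles (>= 2).
#' @param iterations Iteration count.
#' @param inertia Start/end inertia weights, interpolated linearly.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param lower,upper Finite search bounds (log2 space when used for [C, G]).
#' @param seed Seed for particle initialization and updates.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(swarm = 20, iterations = 50, inertia = c(0.9, 0.4),
                       c1 = 2, c2 = 2, lower = c(-5, -15), upper = c(15, 3),
                       seed = 1) {
  stopifnot(swarm >= 2, iterations >= 1, length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)), all(upper >= lower))
  structure(list(swarm = swarm, iterations = iterations, inertia = inertia,
                 c1 = c1, c2 = c2, lower = lower, upper = upper, seed = seed),
            class = "pso_config")
}

#' Maximize an objective with particle swarm optimization
#'
#' Standard global-best PSO over a box: linearly decaying inertia, cognitive
#' and social pulls toward personal and global bests, velocities clamped to
#' the box width and positions clamped to the bounds. The global-best value
#' is monotonically non-decreasing across iterations and every run is
#' deterministic for a fixed seed.
#'
#' @param fn Objective taking a numeric position vector, returning a scalar.
#' @param config A [pso_config()].
#' @return A list: `par`, `value`, `trace` (global best per iteration).
#' @export
pso_maximize <- function(fn, config = pso_config()) {
  lo <- config$lower
  hi <- config$upper
  d <- length(lo)
  if (all(hi == lo)) {
    warn("degenerate PSO bounds: returning the single feasible point")
    return(list(par = lo, value = fn(lo), trace = fn(lo)))
  }
  vmax <- hi - lo
  withr::with_seed(config$seed, {
    pos <- t(replicate(config$swarm, runif(d, lo, hi)))
    vel <- matrix(0, config$swarm, d)
    pval <- apply(pos, 1, fn)
    pbest <- pos
    g <- which.max(pval)
    gbest <- pos[g, ]
    gval <- pval[g]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      w <- config$inertia[1] +
        (config$inertia[2] - config$inertia[1]) * (it - 1) /
        max(1, config$iterations - 1)
      r1 <- matrix(runif(config$swarm * d), config$swarm, d)
      r2 <- matrix(runif(config$swarm * d), config$swarm, d)
      vel <- w * vel + config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * (matrix(gbest, config$swarm, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-vmax, config$swarm, d, byrow = TRUE)),
                  matrix(vmax, config$swarm, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lo, config$swarm, d, byrow = TRUE)),
                  matrix(hi, config$swarm, d, byrow = TRUE))
      val <- apply(pos, 1, fn)
      improved <- val > pval
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pval[improved] <- val[improved]
      if (max(pval) > gval) {
        g <- which.max(pval)
        gval <- pval[g]
        gbest <- pbest[g, ]
      }
      trace[it] <- gval
    }
    list(par = gbest, value = gval, trace = trace)
  })
}

#' Tune [C, G] by particle swarm over cross-validated accuracy
#'
#' Runs [pso_maximize()] in log2([C, G]) space with stratified CV accuracy as
#' the fitness. Typically seeded after a coarse [grid_search()] narrows the
#' region.
#'
#' @inheritParams train_svm
#' @param pso A [pso_config()] (2-dimensional bounds: log2 cost, log2 gamma).
#' @return A list of class `pso_result`: tuned `config`, `cost`, `gamma`,
#'   `accuracy` and the global-best `trace`.
#' @export
pso_optimize <- function(data, config = svm_config(), pso = pso_config(),
                         label_col = "label", standardize = FALSE) {
  stopifnot(length(pso$lower) == 2)
  fn <- function(par) {
    cfg <- config
    cfg$cost <- 2^par[1]
    cfg$gamma <- 2^par[2]
    cross_val_accuracy(data, cfg, label_col, standardize)
  }
  res <- pso_maximize(fn, pso)
  cfg <- config
  cfg$cost <- 2^res$par[1]
  cfg$gamma <- 2^res$par[2]
  structure(list(config = cfg, cost = cfg$cost, gamma = cfg$gamma,
                 accuracy = res$value, trace = res$trace),
            class = "pso_result")
}
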