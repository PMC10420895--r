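#' Tidy a threshold model
#' @param x A `threshold_model`.
#' @param ... Unused.
#' @return One row per peak location with its threshold.
#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(peak = names(x$locations),
         nu1 = map_dbl(x$locations, 1), nu2 = map_dbl(x$locations, 2),
         threshold = unname(x$thresholds), k_sd = x$k_sd)
}

#' Tidy a discriminant model
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return Projected class centroids, one row per class and dimension.
#' @export
tidy.lda_model <- function(x, ...) {
  as_tibble(x$centroids) |>
    mutate(class = x$classes, n = unname(x$counts[x$classes]),
           .before = 1) |>
    tidyr::pivot_longer(-c("class", "n"), names_to = "dimension",
                        values_to = "centroid")
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n = x$n, classes = length(x$classes), m = x$m, ridge = x$ridge,
         method = x$method, trace_ratio = x$trace_ratio)
}

#' One-line summary of an SVM model
#' @param x A `milk_svm`.
#' @param ... Unused.
#' @return A one-row tibble with kernel, cost, gamma and support count.
#' @export
glance.milk_svm <- function(x, ...) {
  tibble(kernel = x$config$kernel, cost = x$config$cost,
         gamma = x$config$gamma, support_count = x$support_count,
         classes = length(x$classes))
}

#' Tidy an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The confusion matrix in long form.
#' @export
tidy.eval_report <- function(x, ...) {
  as_tibble(as.data.frame(as.table(unclass(x$confusion)))) |>
    setNames(c("truth", "estimate", "count"))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  per <- as.list(setNames(x$accuracy_per_class,
                          paste0("accuracy_", names(x$accuracy_per_class))))
  bind_cols(tibble(n = x$n, accuracy_total = x$accuracy_total), as_tibble(per))
}

#' One-line summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A one-row tibble with settings and headline accuracies.
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(seed = x$settings$seed, features = x$settings$features,
         preprocess = x$settings$preprocess,
         classifier = x$settings$classifier,
         cv_accuracy = if (is.null(x$cv_accuracy)) NA_real_ else x$cv_accuracy,
         calibration_accuracy = x$calibration_accuracy,
         validation_accuracy = x$report$accuracy_total)
}
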