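SCHEMA_VERSION <- 1L

#' Write a fitted model or report to JSON
#'
#' Models and evaluation reports are serialized as human-inspectable JSON
#' documents carrying a `schema_version` field. SVM models store their
#' support vectors, dual coefficients and decision offsets; prediction from a
#' read-back model goes through the package's own one-vs-one kernel decision,
#' which is verified against the in-memory predictor in the test suite.
#'
#' @param x A `threshold_model`, `lda_model`, `milk_svm` or `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path) {
  doc <- serialize_model(x)
  doc$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

serialize_model <- function(x) UseMethod("serialize_model")

#' @export
serialize_model.threshold_model <- function(x) {
  list(type = "threshold_model", locations = x$locations,
       thresholds = as.list(x$thresholds), k_sd = x$k_sd,
       reference = x$reference, wavelengths = x$wavelengths,
       n_fresh = x$n_fresh)
}

#' @export
serialize_model.lda_model <- function(x) {
  list(type = "lda_model", V = x$V, classes = x$classes, m = x$m,
       ridge = x$ridge, method = x$method, pca_center = x$pca_center,
       centroids = x$centroids, eigenvalues = x$eigenvalues,
       trace_ratio = x$trace_ratio, feature_names = x$feature_names,
       n = x$n, counts = as.list(x$counts))
}

#' @export
serialize_model.milk_svm <- function(x) {
  p <- svm_parts(x)
  list(type = "milk_svm",
       config = unclass(p$config), SV = p$SV, coefs = p$coefs, rho = p$rho,
       nSV = p$nSV, labels = p$labels, levels = p$levels,
       scaler = x$scaler, feature_names = x$feature_names,
       classes = x$classes, support_count = x$support_count)
}

#' @export
serialize_model.eval_report <- function(x) {
  list(type = "eval_report", classes = rownames(x$confusion),
       confusion = unclass(x$confusion), accuracy_total = x$accuracy_total,
       accuracy_per_class = as.list(x$accuracy_per_class), n = x$n,
       model = x$model)
}

#' Read a model or report back from JSON
#'
#' @param path Path to a document written by [write_model()].
#' @return The reconstructed object.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(doc$schema_version), SCHEMA_VERSION)) {
    stop_lacto("unsupported schema_version", "lacto2dspec_format_error")
  }
  switch(doc$type,
    threshold_model = structure(list(
      locations = lapply(doc$locations, as.numeric),
      thresholds = unlist(doc$thresholds), k_sd = doc$k_sd,
      reference = doc$reference, wavelengths = doc$wavelengths,
      n_fresh = doc$n_fresh), class = "threshold_model"),
    lda_model = {
      v <- as.matrix(doc$V)
      colnames(v) <- paste0("LD", seq_len(doc$m))
      structure(list(
        V = v, classes = doc$classes, m = doc$m, ridge = doc$ridge,
        method = doc$method, pca_center = doc$pca_center,
        centroids = as.matrix(doc$centroids), eigenvalues = doc$eigenvalues,
        trace_ratio = doc$trace_ratio, feature_names = doc$feature_names,
        n = doc$n, counts = unlist(doc$counts)), class = "lda_model")
    },
    milk_svm = {
      cfg <- doc$config
      cfg$gamma <- cfg$gamma %||% NULL
      class(cfg) <- "svm_config"
      parts <- list(SV = as.matrix(doc$SV), coefs = as.matrix(doc$coefs),
                    rho = doc$rho, nSV = doc$nSV, labels = doc$labels,
                    levels = doc$levels, config = cfg)
      scaler <- if (is.null(doc$scaler) || length(doc$scaler) == 0) NULL else {
        list(center = unlist(doc$scaler$center), scale = unlist(doc$scaler$scale))
      }
      structure(list(fit = NULL, parts = parts, config = cfg, scaler = scaler,
                     feature_names = doc$feature_names, classes = doc$classes,
                     support_count = doc$support_count), class = "milk_svm")
    },
    eval_report = {
      cm <- as.matrix(doc$confusion)
      dimnames(cm) <- list(truth = doc$classes, estimate = doc$classes)
      structure(list(
        confusion = structure(cm, class = c("confusion_matrix", "matrix")),
        accuracy_total = doc$accuracy_total,
        accuracy_per_class = unlist(doc$accuracy_per_class), n = doc$n,
        model = doc$model), class = "eval_report")
    },
    stop_lacto("unknown model type", "lacto2dspec_format_error")
  )
}
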