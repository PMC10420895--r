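#' Run the freshness-discrimination pipeline end to end
#'
#' Orchestrates simulate -> split -> reference -> preprocess -> features ->
#' train -> evaluate with a single global seed that fans out deterministically
#' to the per-stage seeds (see [derive_seed()]). All fitting steps (fresh-mean
#' reference, MSC reference, feature standardization, hyperparameter tuning)
#' use calibration samples only; validation samples enter at prediction time.
#'
#' @param seed Global integer seed.
#' @param config A [synth_config()]; its `seed` is overridden by the derived
#'   stage seed. Pass `data` instead to analyse an existing dataset.
#' @param data Optional pre-built, pre-split `spectra_tbl`; when supplied the
#'   simulate stage is skipped.
#' @param features `"corr2d"` (autocorrelation spectra of the single-sample
#'   synchronous maps, the default) or `"visnir"` (plain 1D spectra).
#' @param preprocess_method One of `"raw"`, `"snv"`, `"msc"`, `"deriv1"`.
#' @param preprocess_stage Apply the pretreatment to the 1D spectra before
#'   the 2D transform (default) or to the feature table after it.
#' @param classifier `"svm"`, `"lda"` or `"threshold"`.
#' @param svm An [svm_config()] for the SVM route.
#' @param optimize Hyperparameter search for the SVM route: `"none"`,
#'   `"grid"` or `"grid+pso"`.
#' @param log2_cost,log2_gamma Grid-search axes (log2).
#' @param pso_iterations,pso_swarm PSO budget for the refinement stage.
#' @param out_dir Optional directory; when given, the dataset (CSV), model
#'   (JSON), report (JSON) and an md5 manifest are written there.
#' @return A list of class `pipeline_result`: `report` (validation
#'   [evaluate_predictions()] report), `model`, `calibration_accuracy`,
#'   `cv_accuracy` (SVM route), `data`, `settings`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(seed = 7, config = synth_config(wl_step = 20),
#'                     classifier = "lda")
#' res$report
#' }
run_pipeline <- function(seed = 1, config = synth_config(), data = NULL,
                         features = c("corr2d", "visnir"),
                         preprocess_method = "raw",
                         preprocess_stage = c("before_corr2d", "after_corr2d"),
                         classifier = c("svm", "lda", "threshold"),
                         svm = svm_config(), optimize = "none",
                         log2_cost = seq(-5, 15, by = 2),
                         log2_gamma = seq(-15, 3, by = 2),
                         pso_iterations = 10, pso_swarm = 8,
                         out_dir = NULL) {
  features <- match.arg(features)
  classifier <- match.arg(classifier)
  preprocess_stage <- match.arg(preprocess_stage)
  optimize <- match.arg(optimize, c("none", "grid", "grid+pso"))

  if (is.null(data)) {
    config$seed <- derive_seed(seed, "synth")
    data <- generate_dataset(config)
  }
  cal <- calibration(data)
  val <- validation(data)
  ref <- reference_spectrum(cal, label = "A")
  msc_ref <- colMeans(spectra_matrix(cal)) # frozen calibration mean

  prep <- function(ds) preprocess(ds, preprocess_method, reference = msc_ref)
  featurize <- function(ds) {
    if (features == "visnir") return(prep(ds))
    if (preprocess_stage == "before_corr2d") {
      autocorr_features(prep(ds), prep(ref))
    } else {
      preprocess(autocorr_features(ds, ref), preprocess_method,
                 reference = NULL)
    }
  }
  f_cal <- featurize(cal)
  f_val <- featurize(val)

  cv_acc <- NULL
  tuning <- NULL
  if (classifier == "svm") {
    svm$seed <- derive_seed(seed, "cv")
    if (optimize %in% c("grid", "grid+pso")) {
      gs <- grid_search(f_cal, svm, log2_cost, log2_gamma)
      svm <- gs$config
      tuning <- list(grid = gs$best)
      if (optimize == "grid+pso") {
        step_c <- if (length(log2_cost) > 1) diff(log2_cost)[1] else 1
        step_g <- if (length(log2_gamma) > 1) diff(log2_gamma)[1] else 1
        ps <- pso_optimize(f_cal, svm, pso_config(
          swarm = pso_swarm, iterations = pso_iterations,
          lower = c(gs$best$log2_cost - step_c, gs$best$log2_gamma - step_g),
          upper = c(gs$best$log2_cost + step_c, gs$best$log2_gamma + step_g),
          seed = derive_seed(seed, "pso")))
        if (ps$accuracy >= gs$best$accuracy) svm <- ps$config
        tuning$pso <- ps[c("cost", "gamma", "accuracy")]
      }
    }
    cv_acc <- cross_val_accuracy(f_cal, svm)
    model <- train_svm(f_cal, svm)
    pred_cal <- predict(model, f_cal)$.pred
    pred_val <- predict(model, f_val)$.pred
    truth_cal <- cal$label
    truth_val <- val$label
    classes <- sort(unique(data$label))
  } else if (classifier == "lda") {
    model <- fit_lda(f_cal)
    pred_cal <- predict(model, f_cal)$.pred
    pred_val <- predict(model, f_val)$.pred
    truth_cal <- cal$label
    truth_val <- val$label
    classes <- sort(unique(data$label))
  } else {
    fresh_cal <- cal[cal$label %in% "A", ]
    model <- fit_thresholds(prep(fresh_cal), prep(ref))
    pred_cal <- predict(model, prep(cal))$freshness
    pred_val <- predict(model, prep(val))$freshness
    truth_cal <- ifelse(cal$label == "A", "fresh", "non_fresh")
    truth_val <- ifelse(val$label == "A", "fresh", "non_fresh")
    classes <- c("fresh", "non_fresh")
  }

  report <- evaluate_predictions(truth_val, pred_val, classes,
                                 model = list(classifier = classifier,
                                              features = features,
                                              preprocess = preprocess_method,
                                              seed = seed))
  cal_report <- evaluate_predictions(truth_cal, pred_cal, classes)
  res <- structure(list(
    report = report, calibration_report = cal_report,
    calibration_accuracy = cal_report$accuracy_total,
    cv_accuracy = cv_acc, tuning = tuning, model = model, data = data,
    settings = list(seed = seed, features = features,
                    preprocess = preprocess_method, classifier = classifier,
                    optimize = optimize)
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Pipeline run (seed %d): %s features, %s preprocessing, %s\n",
              s$seed, s$features, s$preprocess, s$classifier))
  if (!is.null(x$cv_accuracy)) {
    cat(sprintf("Calibration CV accuracy: %.1f%%\n", 100 * x$cv_accuracy))
  }
  cat(sprintf("Calibration accuracy: %.1f%%\n", x$calibration_accuracy))
  print(x$report)
  invisible(x)
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dataset = file.path(out_dir, "dataset.csv"),
             model = file.path(out_dir, "model.json"),
             report = file.path(out_dir, "report.json"))
  write_spectra(res$data, paths[["dataset"]])
  write_model(res$model, paths[["model"]])
  write_model(res$report, paths[["report"]])
  manifest <- tibble(artifact = names(paths), path = unname(paths),
                     md5 = unname(tools::md5sum(unname(paths))))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  invisible(out_dir)
}

#' Compare feature spaces and pretreatments
#'
#' Runs the pipeline over the product of feature spaces (1D spectra vs 2D
#' autocorrelation spectra) and pretreatments, returning one row per
#' combination with calibration and validation accuracy — the standard
#' comparison table layout of a preprocessing study.
#'
#' @inheritParams run_pipeline
#' @param preprocess_methods Character vector of pretreatments to sweep.
#' @param feature_spaces Character vector of feature spaces to sweep.
#' @return A tibble with accuracies per combination.
#' @export
compare_feature_spaces <- function(seed = 1, config = synth_config(),
                                   data = NULL,
                                   preprocess_methods = c("raw", "snv", "msc", "deriv1"),
                                   feature_spaces = c("visnir", "corr2d"),
                                   classifier = "lda", svm = svm_config()) {
  if (is.null(data)) {
    config$seed <- derive_seed(seed, "synth")
    data <- generate_dataset(config)
  }
  grid <- tidyr::expand_grid(features = feature_spaces,
                             preprocess = preprocess_methods)
  purrr::pmap(grid, function(features, preprocess) {
    res <- run_pipeline(seed = seed, data = data, features = features,
                        preprocess_method = preprocess,
                        classifier = classifier, svm = svm)
    per_cal <- res$calibration_report$accuracy_per_class
    per_val <- res$report$accuracy_per_class
    tibble(features = features, preprocess = preprocess,
           calibration_accuracy = res$calibration_accuracy,
           validation_accuracy = res$report$accuracy_total,
           calibration_A = per_cal[["A"]], calibration_B = per_cal[["B"]],
           calibration_C = per_cal[["C"]], validation_A = per_val[["A"]],
           validation_B = per_val[["B"]], validation_C = per_val[["C"]])
  }) |> list_rbind()
}
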