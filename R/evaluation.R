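#' Confusion matrix
#'
#' Tabulates true class (rows) against predicted class (columns). Row sums
#' equal the per-class sample counts.
#'
#' @param truth,estimate Label vectors of equal length; every value must be
#'   one of `classes`.
#' @param classes Ordered class labels (default `c("A", "B", "C")`).
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, estimate, classes = c("A", "B", "C")) {
  if (length(truth) != length(estimate)) {
    stop_lacto("truth and estimate lengths differ", "lacto2dspec_input_error")
  }
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad)) {
    stop_lacto(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
               "lacto2dspec_label_error")
  }
  m <- table(factor(truth, levels = classes), factor(estimate, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "estimate")
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Total classification accuracy (percent)
#'
#' `100 * (V_A + V_B + V_C) / (N_A + N_B + N_C)`: correctly classified
#' samples (the confusion-matrix diagonal) over all samples. Full precision is
#' returned; display convention is one decimal place.
#'
#' @param cm A `confusion_matrix`.
#' @return Accuracy in percent.
#' @export
accuracy_total <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop_lacto("empty confusion matrix", "lacto2dspec_input_error")
  100 * sum(diag(unclass(cm))) / n
}

#' Per-class classification accuracy (percent)
#'
#' `100 * V_class / N_class` for every class present in the truth; classes
#' with no samples are omitted rather than reported as 0%.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector of percentages.
#' @export
accuracy_per_class <- function(cm) {
  m <- unclass(cm)
  n_class <- rowSums(m)
  keep <- n_class > 0
  100 * diag(m)[keep] / n_class[keep]
}

#' Coefficient of variation
#'
#' Sample standard deviation over mean, the dispersion measure used for
#' storage-stable quality indicators (fat, protein, relative density have
#' CV < 0.02 over six days; acidity does not).
#'
#' @param values Numeric vector with at least 2 values and nonzero mean.
#' @return SD/mean ratio.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    stop_lacto("need at least 2 values", "lacto2dspec_input_error")
  }
  m <- mean(values)
  if (m == 0) stop_lacto("zero mean: CV undefined", "lacto2dspec_input_error")
  sd(values) / m
}

#' Map titratable acidity to a freshness class
#'
#' Fresh A for acidity in `[13, 15)` degrees T, sub-fresh B for `[15, 18]`,
#' spoiled C above 18. The spoiled class is strictly `> 18`, which forces 18
#' into B; 15 is assigned to B so both non-fresh classes have closed lower
#' bounds. Acidity below 13 is outside the scheme and raises an error.
#'
#' @param acidity Acidity in Thorner degrees (vectorized).
#' @return Character vector of labels.
#' @export
#' @examples
#' label_from_acidity(c(14.1, 15, 18, 21))
label_from_acidity <- function(acidity) {
  if (any(acidity < 13)) {
    stop_lacto("acidity below 13 degrees T is outside the labelling scheme",
               "lacto2dspec_range_error")
  }
  ifelse(acidity < 15, "A", ifelse(acidity <= 18, "B", "C"))
}

#' Evaluate predictions into an accuracy report
#'
#' Bundles the confusion matrix with total and per-class accuracies. The
#' total accuracy is checked against the count-weighted mean of the per-class
#' accuracies (an algebraic identity) on every construction.
#'
#' @inheritParams confusion_matrix
#' @param model Optional metadata list recorded verbatim.
#' @return A list of class `eval_report`.
#' @export
evaluate_predictions <- function(truth, estimate, classes = c("A", "B", "C"),
                                 model = NULL) {
  cm <- confusion_matrix(truth, estimate, classes)
  total <- accuracy_total(cm)
  per_class <- accuracy_per_class(cm)
  n_class <- rowSums(unclass(cm))[rowSums(unclass(cm)) > 0]
  stopifnot(isTRUE(all.equal(total, sum(per_class * n_class) / sum(n_class))))
  structure(list(confusion = cm, accuracy_total = total,
                 accuracy_per_class = per_class, n = sum(cm), model = model),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Freshness evaluation report\n")
  print(unclass(x$confusion))
  cat(sprintf("Total accuracy: %.1f%%\n", x$accuracy_total))
  cat("Per class:",
      paste(sprintf("%s %.1f%%", names(x$accuracy_per_class),
                    x$accuracy_per_class), collapse = ", "), "\n")
  invisible(x)
}
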