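#' Published quality indicators of raw milk over six days of refrigerated
#' storage
#'
#' Summary statistics of the physicochemical indicators tracked in a six-day
#' refrigerated raw-milk storage benchmark: range of variation, mean, sample
#' standard deviation and coefficient of variation (SD/mean). Fat, protein
#' and relative density are storage-stable (CV < 0.02); titratable acidity
#' rises from 14.1 to 21.0 Thorner degrees and lactose falls as it is
#' fermented to lactic acid. These figures calibrate the synthetic generator
#' and anchor the arithmetic checks of the evaluation module.
#'
#' @format A tibble with one row per indicator: `indicator`, `unit`, `lower`,
#'   `upper`, `mean`, `sd`, `cv`.
#' @export
milk_quality_indicators <- tibble::tribble(
  ~indicator,         ~unit,          ~lower,  ~upper,  ~mean,  ~sd,     ~cv,
  "fat",              "%",            3.70,    3.93,    3.78,   0.0711,  0.0188,
  "protein",          "%",            3.72,    3.76,    3.74,   0.0127,  0.0034,
  "lactose",          "%",            5.03,    5.35,    5.15,   0.1117,  0.0217,
  "acidity",          "degrees T",    14.1,    21.0,    16.3,   2.2904,  0.1408,
  "relative_density", "20 C / 4 C",   1.032,   1.034,   1.033,  0.0007,  0.0007
)

#' Benchmark SVM calibration results by kernel and feature space
#'
#' Calibration-set results of the same benchmark's SVM models: per-kernel
#' confusion-matrix diagonals (correctly classified counts per class),
#' support-vector counts and reported total accuracy, for models trained on
#' plain Vis/NIR spectra and on synchronous 2D autocorrelation features. The
#' calibration set held 97 samples: 27 fresh (A), 43 sub-fresh (B) and 27
#' spoiled (C). The diagonals plus class sizes are internally consistent with
#' the reported accuracies and are what the acceptance checks recompute.
#'
#' @format A tibble: `feature_space`, `kernel`, `correct_a`, `correct_b`,
#'   `correct_c`, `n_a`, `n_b`, `n_c`, `support_vectors`,
#'   `reported_accuracy` (percent, one decimal).
#' @export
milk_svm_benchmark <- tibble::tribble(
  ~feature_space, ~kernel,      ~correct_a, ~correct_b, ~correct_c, ~support_vectors, ~reported_accuracy,
  "visnir",       "linear",     27, 40, 27, 18, 96.9,
  "visnir",       "polynomial", 27, 39, 26, 21, 94.8,
  "visnir",       "rbf",        27, 41, 27, 24, 97.9,
  "visnir",       "sigmoid",    27, 39, 27, 20, 95.9,
  "corr2d",       "linear",     27, 42, 27, 10, 99.0,
  "corr2d",       "polynomial", 27, 43, 25,  7, 97.9,
  "corr2d",       "rbf",        27, 43, 27,  6, 100.0,
  "corr2d",       "sigmoid",    27, 43, 26,  6, 99.0
) |> dplyr::mutate(n_a = 27, n_b = 43, n_c = 27, .after = "correct_c")

#' Expand benchmark diagonals into a confusion matrix
#'
#' Builds a valid [confusion_matrix()] from per-class correct counts and
#' class sizes; samples missed in a class are placed in the adjacent class
#' (B misses to C, C misses to B), which leaves the diagonal — the quantity
#' the accuracy formulas consume — exact.
#'
#' @param correct Named or positional vector of per-class correct counts.
#' @param n Per-class sample counts (same order).
#' @param classes Class labels.
#' @return A `confusion_matrix`.
#' @export
benchmark_confusion <- function(correct, n, classes = c("A", "B", "C")) {
  stopifnot(length(correct) == length(n), all(correct <= n))
  k <- length(classes)
  m <- matrix(0L, k, k, dimnames = list(truth = classes, estimate = classes))
  for (i in seq_len(k)) {
    m[i, i] <- as.integer(correct[i])
    spill <- if (i < k) i + 1 else i - 1
    m[i, spill] <- m[i, spill] + as.integer(n[i] - correct[i])
  }
  structure(m, class = c("confusion_matrix", "matrix"))
}
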