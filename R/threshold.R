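default_peak_locations <- function() {
  list(auto_1450 = c(1450, 1450),
       auto_1940 = c(1940, 1940),
       cross_1450_1940 = c(1450, 1940))
}

#' Synchronous peak series for a dataset
#'
#' For each sample, the values of its single-sample synchronous map at a set
#' of wavelength pairs: by default the two water autocorrelation peaks
#' (1450, 1450) and (1940, 1940) and their cross peak (1450, 1940). Computed
#' directly as products of the dynamic spectrum, without materializing the
#' full matrices.
#'
#' @param ds A `spectra_tbl`.
#' @param reference Reference spectrum (fresh-mean).
#' @param locations Named list of `c(nu1, nu2)` pairs in nm.
#' @return A tibble with `sample_id`, `storage_time`, `label` and one column
#'   per location.
#' @export
peak_series <- function(ds, reference, locations = default_peak_locations()) {
  d <- spectra_matrix(dynamic_spectra(ds, reference))
  wl <- spec_wavelengths(ds)
  snap <- function(nu) {
    if (nu < min(wl) || nu > max(wl)) {
      stop_lacto(sprintf("wavelength %g nm outside grid", nu),
                 "lacto2dspec_range_error")
    }
    which.min(abs(wl - nu))
  }
  vals <- lapply(locations, function(loc) d[, snap(loc[1])] * d[, snap(loc[2])])
  bind_cols(tibble(sample_id = ds$sample_id, storage_time = ds$storage_time,
                   label = ds$label),
            as_tibble(vals))
}

#' Fit peak thresholds on fresh calibration samples
#'
#' The discrimination threshold at each peak location is
#' `mean + k_sd * SD` of the fresh calibration samples' peak values
#' (default `k_sd = 3`). Fresh milk scatters tightly around the fresh-mean
#' reference, so these thresholds sit just above the fresh envelope; any
#' sample exceeding a threshold at any location is called non-fresh.
#'
#' @param fresh_cal A `spectra_tbl` of fresh (class A) calibration samples,
#'   at least 2.
#' @param reference Reference spectrum the thresholds are defined against.
#' @param k_sd SD multiplier (default 3).
#' @param locations Named list of `c(nu1, nu2)` peak locations in nm.
#' @return A list of class `threshold_model`.
#' @export
fit_thresholds <- function(fresh_cal, reference, k_sd = 3,
                           locations = default_peak_locations()) {
  if (nrow(fresh_cal) < 2) {
    stop_lacto("need at least 2 fresh calibration samples",
               "lacto2dspec_input_error")
  }
  ps <- peak_series(fresh_cal, reference, locations)
  peaks <- as.matrix(ps[names(locations)])
  thresholds <- colMeans(peaks) + k_sd * apply(peaks, 2, sd)
  structure(list(locations = locations, thresholds = thresholds, k_sd = k_sd,
                 reference = ref_vector(fresh_cal, reference),
                 wavelengths = spec_wavelengths(fresh_cal),
                 n_fresh = nrow(fresh_cal)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Peak-threshold freshness model (k_sd = %g, %d fresh samples)\n",
              x$k_sd, x$n_fresh))
  print(signif(x$thresholds, 4))
  invisible(x)
}

#' Classify samples with a fitted threshold model
#'
#' A sample is called `fresh` iff all of its synchronous peak values are at or
#' below their thresholds; otherwise `non_fresh`. This is a binary rule: the
#' peak magnitudes separate fresh from non-fresh well but are too noisy to
#' resolve sub-fresh from spoiled.
#'
#' @param object A `threshold_model`.
#' @param newdata A `spectra_tbl` on the fitting grid.
#' @param ... Unused.
#' @return A tibble with `sample_id`, the peak values and `freshness`.
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  if (!isTRUE(all.equal(spec_wavelengths(newdata), object$wavelengths))) {
    stop_lacto("newdata grid differs from the fitting grid",
               "lacto2dspec_grid_error")
  }
  ps <- peak_series(newdata, object$reference, object$locations)
  peaks <- as.matrix(ps[names(object$locations)])
  ok <- sweep(peaks, 2, object$thresholds, "<=")
  ps$freshness <- ifelse(rowSums(!ok) == 0, "fresh", "non_fresh")
  ps
}

#' Peak intensity versus storage time regression
#'
#' Ordinary least squares of peak intensity on storage time, with
#' `R^2 = 1 - SS_res / SS_tot`. The water-band peaks grow roughly linearly
#' with storage time, so this regression gives a crude storage-time (hence
#' freshness) predictor.
#'
#' @param data A data frame with the two variables.
#' @param time,intensity Column names (defaults `storage_time` and the first
#'   non-time numeric column).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
peak_time_regression <- function(data, time = "storage_time",
                                 intensity = NULL) {
  if (is.null(intensity)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], time)
    intensity <- candidates[1]
  }
  t <- data[[time]]
  y <- data[[intensity]]
  if (length(t) < 3) {
    stop_lacto("need at least 3 points", "lacto2dspec_input_error")
  }
  if (length(unique(t)) < 2) {
    stop_lacto("all times equal: slope undefined", "lacto2dspec_input_error")
  }
  fit <- lm(y ~ t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  # exactly constant intensity: nothing to explain, R^2 reported as 0
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
         n = length(y))
}
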