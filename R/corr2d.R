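#' Mean fresh-milk reference spectrum
#'
#' The reference for all 2D correlation operations is the pointwise mean of
#' the fresh (class A) spectra. Pass a calibration subset to keep validation
#' samples out of the reference.
#'
#' @param ds A `spectra_tbl` containing at least one spectrum with the target
#'   label.
#' @param label Class treated as fresh (default `"A"`). Use `NULL` to average
#'   every row of `ds` regardless of label.
#' @return A one-row `spectra_tbl` with `sample_id = "reference"`.
#' @export
reference_spectrum <- function(ds, label = "A") {
  keep <- if (is.null(label)) rep(TRUE, nrow(ds)) else ds$label %in% label
  if (!any(keep)) {
    stop_lacto("no spectra available for the reference", "lacto2dspec_input_error")
  }
  m <- colMeans(spectra_matrix(ds[keep, ]))
  spectra_tbl(m, spec_wavelengths(ds), sample_id = "reference")
}

ref_vector <- function(ds, reference) {
  wl <- spec_wavelengths(ds)
  if (inherits(reference, "spectra_tbl") || is.data.frame(reference)) {
    rwl <- as.numeric(wavelength_names(reference))
    if (!isTRUE(all.equal(rwl, wl))) {
      stop_lacto("reference and dataset grids differ", "lacto2dspec_grid_error")
    }
    colMeans(spectra_matrix(as_spectra(reference)))
  } else {
    if (length(reference) != length(wl)) {
      stop_lacto("reference and dataset grids differ", "lacto2dspec_grid_error")
    }
    as.numeric(reference)
  }
}

#' Dynamic spectra relative to a reference
#'
#' The dynamic spectrum of a sample is its pointwise deviation from the
#' reference spectrum; all 2D correlation intensities are built from it.
#'
#' @param ds A `spectra_tbl`.
#' @param reference A one-row `spectra_tbl` or numeric vector on the same grid.
#' @return A `spectra_tbl` of deviations (same metadata).
#' @export
dynamic_spectra <- function(ds, reference) {
  r <- ref_vector(ds, reference)
  set_absorbance(ds, sweep(spectra_matrix(ds), 2, r))
}

new_sync_corr <- function(values, wavelengths, kind = "synchronous") {
  dimnames(values) <- list(wavelengths, wavelengths)
  structure(values, wavelengths = as.numeric(wavelengths), kind = kind,
            class = "sync_corr")
}

#' @export
print.sync_corr <- function(x, ...) {
  wl <- attr(x, "wavelengths")
  cat(sprintf("<%s 2D correlation matrix: %d x %d, %g-%g nm>\n",
              attr(x, "kind"), nrow(x), ncol(x), min(wl), max(wl)))
  invisible(x)
}

#' Synchronous 2D correlation matrix of a single sample
#'
#' For one sample the synchronous map is the outer product of its dynamic
#' spectrum with itself: `Phi(v1, v2) = y(v1) * y(v2)` with
#' `y = sample - reference`. It is symmetric, its diagonal (the
#' autocorrelation spectrum) is the squared dynamic spectrum, and it is
#' exactly zero when the sample equals the reference — the behaviour expected
#' of fresh milk measured against the fresh-mean reference. This per-sample
#' map is the default feature source for classification (one feature vector
#' per sample).
#'
#' @param x A one-row `spectra_tbl` (or a numeric spectrum on the reference
#'   grid).
#' @param reference Reference spectrum (one-row `spectra_tbl` or numeric).
#' @return A `sync_corr` matrix (wavelength x wavelength, absorbance squared).
#' @export
sync_single <- function(x, reference) {
  if (inherits(x, "spectra_tbl") || is.data.frame(x)) {
    x <- as_spectra(x)
    if (nrow(x) != 1) {
      stop_lacto("sync_single() expects a single spectrum", "lacto2dspec_input_error")
    }
    wl <- spec_wavelengths(x)
    v <- drop(spectra_matrix(x)) - ref_vector(x, reference)
  } else {
    r <- if (is.data.frame(reference)) colMeans(spectra_matrix(as_spectra(reference))) else as.numeric(reference)
    if (length(x) != length(r)) {
      stop_lacto("spectrum and reference grids differ", "lacto2dspec_grid_error")
    }
    wl <- if (is.data.frame(reference)) as.numeric(wavelength_names(reference)) else seq_along(r)
    v <- as.numeric(x) - r
  }
  new_sync_corr(tcrossprod(v), wl)
}

#' Ensemble synchronous 2D correlation matrix
#'
#' The generalized (Noda) synchronous estimator over a group of m >= 2
#' spectra: `Phi(v1, v2) = 1/(m-1) * sum_j y_j(v1) y_j(v2)` over the group's
#' dynamic spectra. The result is symmetric positive semidefinite. Use it to
#' reproduce per-storage-day correlation maps from replicate sets.
#'
#' @param ds A `spectra_tbl` with at least 2 rows.
#' @param reference Reference spectrum.
#' @return A `sync_corr` matrix.
#' @export
sync_ensemble <- function(ds, reference) {
  if (nrow(ds) < 2) {
    stop_lacto("ensemble estimator needs at least 2 spectra",
               "lacto2dspec_input_error")
  }
  d <- spectra_matrix(dynamic_spectra(ds, reference))
  new_sync_corr(crossprod(d) / (nrow(d) - 1), spec_wavelengths(ds))
}

#' Ensemble asynchronous 2D correlation matrix
#'
#' The asynchronous counterpart, `Psi = 1/(m-1) * t(Y) N Y` with the
#' Hilbert-Noda matrix `N[j,k] = 0` if `j = k`, else `1 / (pi * (k - j))`.
#' Antisymmetric with a zero diagonal; it resolves the sequential order of
#' intensity changes and is provided as an optional companion to the
#' synchronous maps.
#'
#' @param ds A `spectra_tbl` with at least 3 rows, ordered along the
#'   perturbation (e.g. storage time).
#' @param reference Reference spectrum.
#' @return A `sync_corr` matrix with `kind = "asynchronous"`.
#' @export
async_ensemble <- function(ds, reference) {
  m <- nrow(ds)
  if (m < 3) {
    stop_lacto("asynchronous estimator needs at least 3 spectra",
               "lacto2dspec_input_error")
  }
  d <- spectra_matrix(dynamic_spectra(ds, reference))
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  noda <- ifelse(jk == 0, 0, 1 / (pi * jk))
  new_sync_corr(t(d) %*% noda %*% d / (m - 1), spec_wavelengths(ds),
                kind = "asynchronous")
}

#' Autocorrelation spectrum (matrix diagonal)
#'
#' Diagonal of a synchronous map: the total intensity fluctuation at each
#' wavelength, always non-negative.
#'
#' @param m A `sync_corr` matrix.
#' @return A tibble with `wavelength` and `intensity`.
#' @export
autocorrelation <- function(m) {
  stopifnot(inherits(m, "sync_corr"))
  tibble(wavelength = attr(m, "wavelengths"),
         intensity = unname(diag(unclass(m))))
}

#' Per-sample autocorrelation features
#'
#' Classifier features from the 2D representation: for each sample, the
#' diagonal of its single-sample synchronous map, which is algebraically the
#' squared dynamic spectrum. Returns a spectra-shaped tibble (values in
#' absorbance squared) so the downstream model functions apply unchanged.
#'
#' @param ds A `spectra_tbl`.
#' @param reference Reference spectrum (typically the calibration fresh mean).
#' @return A `spectra_tbl` of autocorrelation intensities.
#' @export
autocorr_features <- function(ds, reference) {
  d <- dynamic_spectra(ds, reference)
  set_absorbance(d, spectra_matrix(d)^2)
}

#' Look up a correlation peak
#'
#' Value of a 2D map at a wavelength pair, snapped to the nearest grid points
#' (ties resolved toward the lower wavelength). Symmetric in its arguments for
#' synchronous maps by construction.
#'
#' @param m A `sync_corr` matrix.
#' @param nu1,nu2 Wavelengths in nm; must lie within the grid range.
#' @return The correlation intensity at the snapped pair.
#' @export
peak_value <- function(m, nu1, nu2) {
  wl <- attr(m, "wavelengths")
  snap <- function(nu) {
    if (nu < min(wl) || nu > max(wl)) {
      stop_lacto(sprintf("wavelength %g nm outside grid [%g, %g]",
                         nu, min(wl), max(wl)), "lacto2dspec_range_error")
    }
    which.min(abs(wl - nu)) # ties: first index = lower wavelength
  }
  unclass(m)[snap(nu1), snap(nu2)]
}
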