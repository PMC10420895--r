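#' Spectral pretreatments
#'
#' Three pretreatments commonly compared in Vis/NIR chemometrics, applied row
#' by row to a spectra table:
#'
#' * **SNV** (standard normal variate): each spectrum is centred and scaled to
#'   unit sample standard deviation across wavelengths, suppressing
#'   multiplicative scatter and baseline offsets.
#' * **MSC** (multiplicative scatter correction): each spectrum `x` is
#'   regressed on a reference spectrum, `x ~ a * ref + b`, and replaced by
#'   `(x - b) / a`. The reference defaults to the calibration-set mean (or the
#'   whole-set mean when no split is assigned) and should be frozen into any
#'   fitted model so validation samples are corrected with calibration
#'   parameters only.
#' * **deriv1**: Savitzky-Golay first derivative in absorbance per nm,
#'   same-length output with polynomial fits at the boundaries.
#'
#' @param ds A `spectra_tbl`.
#' @param method One of `"raw"`, `"snv"`, `"msc"`, `"deriv1"`.
#' @param reference Optional reference for MSC: a one-row `spectra_tbl` or a
#'   numeric vector on the same grid.
#' @param window Odd Savitzky-Golay window length in points (default 11).
#' @param polyorder Savitzky-Golay polynomial order (default 2); the window
#'   must be at least `polyorder + 2`.
#' @return A `spectra_tbl` on the same grid with transformed absorbances.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_samples = 13, wl_step = 50))
#' preprocess(ds, "snv")
preprocess <- function(ds, method = c("raw", "snv", "msc", "deriv1"),
                       reference = NULL, window = 11, polyorder = 2) {
  method <- match.arg(method)
  switch(method,
    raw = ds,
    snv = snv(ds),
    msc = msc(ds, reference = reference),
    deriv1 = first_derivative(ds, window = window, polyorder = polyorder)
  )
}

set_absorbance <- function(ds, m) {
  ds[wavelength_names(ds)] <- as_tibble(m, .name_repair = "minimal")
  ds
}

#' @rdname preprocess
#' @export
snv <- function(ds) {
  x <- spectra_matrix(ds)
  if (ncol(x) < 2) {
    stop_lacto("SNV needs at least 2 wavelengths", "lacto2dspec_degenerate_error")
  }
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    stop_lacto("constant spectrum: SNV undefined (sd = 0)",
               "lacto2dspec_degenerate_error")
  }
  set_absorbance(ds, (x - rowMeans(x)) / s)
}

resolve_reference <- function(ds, reference) {
  if (is.null(reference)) {
    has_cal <- any(ds$split %in% "calibration")
    base <- if (has_cal) ds[ds$split %in% "calibration", ] else ds
    return(colMeans(spectra_matrix(base)))
  }
  if (inherits(reference, "spectra_tbl") || is.data.frame(reference)) {
    if (!identical(as.numeric(wavelength_names(reference)), spec_wavelengths(ds))) {
      stop_lacto("reference is not on the dataset grid", "lacto2dspec_grid_error")
    }
    return(colMeans(spectra_matrix(as_spectra(reference))))
  }
  if (length(reference) != length(spec_wavelengths(ds))) {
    stop_lacto("reference length does not match the grid", "lacto2dspec_grid_error")
  }
  as.numeric(reference)
}

#' @rdname preprocess
#' @export
msc <- function(ds, reference = NULL) {
  r <- resolve_reference(ds, reference)
  if (sd(r) == 0) {
    stop_lacto("constant reference: MSC undefined", "lacto2dspec_degenerate_error")
  }
  x <- spectra_matrix(ds)
  rc <- r - mean(r)
  denom <- sum(rc^2)
  a <- as.numeric((x %*% rc)) / denom # per-row slope of x on r
  b <- rowMeans(x) - a * mean(r)
  if (any(abs(a) < .Machine$double.eps)) {
    stop_lacto("degenerate MSC fit (slope ~ 0)", "lacto2dspec_degenerate_error")
  }
  set_absorbance(ds, (x - b) / a)
}

#' @rdname preprocess
#' @export
first_derivative <- function(ds, window = 11, polyorder = 2) {
  wl <- spec_wavelengths(ds)
  if (window %% 2 != 1 || window < polyorder + 2 || window > length(wl)) {
    stop_lacto("window must be odd, >= polyorder + 2 and <= grid length",
               "lacto2dspec_config_error")
  }
  if (!is_uniform_grid(wl)) {
    stop_lacto("Savitzky-Golay derivative requires a uniform grid",
               "lacto2dspec_grid_error")
  }
  step <- if (length(wl) > 1) wl[2] - wl[1] else 1
  x <- spectra_matrix(ds)
  d <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window, m = 1,
               ts = step))
  set_absorbance(ds, d)
}
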