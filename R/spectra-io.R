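#' Coerce a wide data frame to a spectra table
#'
#' The package's central container is an ordinary tibble in "wide" layout: one
#' row per sample, metadata columns first (`sample_id`, `storage_time` in
#' hours, `acidity` in Thorner degrees, `label` in A/B/C, `split`), then one
#' numeric column per wavelength, named by its nm value. `as_spectra()`
#' validates that layout: the wavelength grid must be strictly increasing and
#' sample ids unique. Missing metadata columns are added as `NA` (prediction-
#' only use is allowed; classifiers that need labels raise their own errors).
#'
#' @param df A data frame with a `sample_id` column and numeric wavelength
#'   columns.
#' @return A tibble of class `spectra_tbl`.
#' @export
#' @examples
#' as_spectra(data.frame(sample_id = "s1", `400` = 0.1, `402` = 0.2,
#'                       check.names = FALSE))
as_spectra <- function(df) {
  df <- as_tibble(df)
  if (!"sample_id" %in% names(df)) {
    stop_lacto("`sample_id` column is required", "lacto2dspec_format_error")
  }
  df$sample_id <- as.character(df$sample_id)
  wl_nm <- wavelength_names(df)
  if (length(wl_nm) < 1) {
    stop_lacto("no wavelength columns found (numeric column names)",
               "lacto2dspec_format_error")
  }
  wl <- as.numeric(wl_nm)
  if (any(diff(wl) <= 0)) {
    stop_lacto("wavelength grid must be strictly increasing",
               "lacto2dspec_grid_error")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_lacto("duplicate sample_id values", "lacto2dspec_uniqueness_error")
  }
  for (m in .meta_cols) {
    if (!m %in% names(df)) {
      df[[m]] <- if (m %in% c("storage_time", "acidity")) NA_real_ else NA_character_
    }
  }
  bad <- !vapply(df[wl_nm], is.numeric, logical(1))
  if (any(bad)) {
    stop_lacto("wavelength columns must be numeric", "lacto2dspec_format_error")
  }
  out <- df[c(.meta_cols, wl_nm)]
  class(out) <- c("spectra_tbl", class(out))
  out
}

#' Build a spectra table from an absorbance matrix
#'
#' @param absorbance Numeric matrix, samples in rows.
#' @param wavelengths Strictly increasing nm grid, one per column.
#' @param sample_id Character ids (default `s1`, `s2`, ...).
#' @param storage_time,acidity,label,split Optional per-sample metadata.
#' @return A `spectra_tbl`.
#' @export
spectra_tbl <- function(absorbance, wavelengths,
                        sample_id = paste0("s", seq_len(nrow(absorbance))),
                        storage_time = NA_real_, acidity = NA_real_,
                        label = NA_character_, split = NA_character_) {
  absorbance <- rbind(absorbance)
  stopifnot(ncol(absorbance) == length(wavelengths))
  df <- as_tibble(absorbance, .name_repair = "minimal")
  names(df) <- as.character(wavelengths)
  df <- bind_cols(
    tibble(sample_id = sample_id,
           storage_time = as.double(storage_time),
           acidity = as.double(acidity),
           label = as.character(label),
           split = as.character(split)),
    df
  )
  as_spectra(df)
}

#' Wavelength grid of a spectra table
#' @param ds A `spectra_tbl`.
#' @return Numeric vector of wavelengths in nm.
#' @export
spec_wavelengths <- function(ds) {
  as.numeric(wavelength_names(ds))
}

#' Absorbance matrix of a spectra table
#' @param ds A `spectra_tbl`.
#' @return Numeric matrix (samples x wavelengths) with sample ids as rownames.
#' @export
spectra_matrix <- function(ds) {
  m <- as.matrix(ds[wavelength_names(ds)])
  rownames(m) <- ds$sample_id
  m
}

#' Read spectra from a wide CSV file
#'
#' Expects the dialect written by [write_spectra()]: metadata columns then one
#' column per wavelength named by its nm value, UTF-8, '.' decimal separator.
#'
#' @param path Path to a CSV file.
#' @return A `spectra_tbl`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) {
    stop_lacto(paste0("file not found: ", path), "lacto2dspec_format_error")
  }
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  if (nrow(readr::problems(df)) > 0) {
    stop_lacto("malformed CSV (ragged rows or unparseable fields)",
               "lacto2dspec_format_error")
  }
  as_spectra(df)
}

#' Write spectra to a wide CSV file
#' @param ds A `spectra_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  readr::write_csv(ds, path, progress = FALSE)
  invisible(path)
}

#' Assign a calibration/validation split
#'
#' Tags exactly `n_calibration` samples as `"calibration"` and the rest as
#' `"validation"`. Under stratification the per-class calibration counts follow
#' largest-remainder apportionment of class proportions, so each class is
#' preserved to within one sample. Deterministic for a fixed seed.
#'
#' @param ds A `spectra_tbl`.
#' @param n_calibration Number of calibration samples (default 97, against a
#'   130-sample design).
#' @param seed Integer seed controlling the random assignment.
#' @param stratify Preserve per-class proportions (requires labels; every class
#'   must have at least 2 members).
#' @return `ds` with its `split` column filled.
#' @export
split_dataset <- function(ds, n_calibration = 97, seed = 1, stratify = TRUE) {
  n <- nrow(ds)
  if (!(n_calibration > 0 && n_calibration < n)) {
    stop_lacto("`n_calibration` must lie strictly between 0 and the sample count",
               "lacto2dspec_split_error")
  }
  idx_cal <- withr::with_seed(seed, {
    if (stratify) {
      if (anyNA(ds$label)) {
        stop_lacto("stratified split requires a label for every sample",
                   "lacto2dspec_stratification_error")
      }
      counts <- table(ds$label)
      if (any(counts < 2)) {
        stop_lacto("every class needs at least 2 members for stratification",
                   "lacto2dspec_stratification_error")
      }
      quota <- n_calibration * as.numeric(counts) / n
      base <- floor(quota)
      rem <- n_calibration - sum(base)
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
      unlist(lapply(seq_along(counts), function(i) {
        members <- which(ds$label == names(counts)[i])
        sample(members, base[i])
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), n_calibration)
    }
  })
  ds$split <- "validation"
  ds$split[idx_cal] <- "calibration"
  ds
}

#' Calibration / validation subsets
#' @param ds A split `spectra_tbl`.
#' @return The subset of rows tagged `"calibration"` (or `"validation"`).
#' @export
calibration <- function(ds) {
  if (all(is.na(ds$split))) {
    stop_lacto("dataset has no split assignment; call split_dataset() first",
               "lacto2dspec_split_error")
  }
  ds[ds$split %in% "calibration", ]
}

#' @rdname calibration
#' @export
validation <- function(ds) {
  if (all(is.na(ds$split))) {
    stop_lacto("dataset has no split assignment; call split_dataset() first",
               "lacto2dspec_split_error")
  }
  ds[ds$split %in% "validation", ]
}
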