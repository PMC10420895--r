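# Metadata columns reserved in the wide spectra dialect; everything else whose
# name parses as a number is a wavelength column.
.meta_cols <- c("sample_id", "storage_time", "acidity", "label", "split")

stop_lacto <- function(message, class, ...) {
  abort(message, class = c(class, "lacto2dspec_error"), ...)
}

#' Derive a stage seed from a global seed
#'
#' One user-facing seed fans out deterministically to per-stage seeds so that a
#' single integer reproduces a whole pipeline run. The derived seed is always a
#' non-negative integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param salt Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "split")
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(salt))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((abs(seed) * 48271 + h * 9973) %% 2147483647L)
}

# Names of the wavelength columns of a wide spectra data frame, in file order.
wavelength_names <- function(df) {
  nm <- setdiff(names(df), .meta_cols)
  nm[!is.na(suppressWarnings(as.numeric(nm)))]
}

is_uniform_grid <- function(wl, tol = 1e-8) {
  if (length(wl) < 3) return(TRUE)
  d <- diff(wl)
  max(d) - min(d) < tol
}
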