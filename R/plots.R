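#' Plot spectra coloured by storage time or class
#'
#' @param object A `spectra_tbl`.
#' @param colour Metadata column mapped to colour (default `storage_time`).
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_tbl <- function(object, colour = "storage_time",
                                 alpha = 0.6, ...) {
  long <- tidyr::pivot_longer(object, cols = all_of(wavelength_names(object)),
                              names_to = "wavelength",
                              values_to = "absorbance") |>
    mutate(wavelength = as.numeric(.data$wavelength))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$sample_id,
                                     colour = .data[[colour]])) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance") +
    ggplot2::theme_minimal()
}

#' Plot a 2D correlation map
#'
#' Raster view of a synchronous (or asynchronous) wavelength-by-wavelength
#' correlation matrix with a diverging fill centred at zero.
#'
#' @param object A `sync_corr` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sync_corr <- function(object, ...) {
  wl <- attr(object, "wavelengths")
  df <- tidyr::expand_grid(nu1 = wl, nu2 = wl)
  df$intensity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$nu1, .data$nu2,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red3") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "wavelength (nm)", y = "wavelength (nm)",
                  fill = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Total accuracy %.1f%%",
                                  object$accuracy_total)) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter search surface
#'
#' Cross-validated accuracy over the log2([C, G]) grid, with the selected
#' optimum marked.
#'
#' @param object A `grid_search` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_search <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$log2_cost, .data$log2_gamma,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, colour = "red", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "log2 C", y = "log2 G", fill = "CV accuracy") +
    ggplot2::theme_minimal()
}

#' Peak intensity against storage time
#'
#' Scatter of the synchronous peak values from [peak_series()] against
#' storage time with the least-squares line, one panel per peak.
#'
#' @param series Output of [peak_series()].
#' @return A ggplot.
#' @export
plot_peak_trends <- function(series) {
  long <- tidyr::pivot_longer(series,
                              cols = -c("sample_id", "storage_time", "label"),
                              names_to = "peak", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$storage_time, .data$intensity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::facet_wrap(~peak, scales = "free_y") +
    ggplot2::labs(x = "storage time (h)", y = "correlation intensity") +
    ggplot2::theme_minimal()
}
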