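# Small fixtures shared across the suite. Generator tests use a coarse grid
# (10 nm steps, 211 points) so each case runs in milliseconds; the acceptance
# suite exercises the full 1051-point default design.

small_config <- function(seed = 1, wl_step = 10, ...) {
  synth_config(wl_step = wl_step, seed = seed, ...)
}

tiny_spectra <- function(values, wl = NULL, ...) {
  values <- rbind(values)
  wl <- wl %||% seq_len(ncol(values))
  spectra_tbl(values, wl, ...)
}

# Deterministic three-class Gaussian blobs for classifier tests.
gaussian_blobs <- function(n_per_class = 20, d = 4, sep = 6, sd = 1,
                           seed = 42) {
  withr::with_seed(seed, {
    centers <- rbind(A = c(rep(0, d)),
                     B = c(sep, rep(0, d - 1)),
                     C = c(0, sep, rep(0, d - 2)))
    x <- do.call(rbind, lapply(rownames(centers), function(cl) {
      matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
        matrix(centers[cl, ], n_per_class, d, byrow = TRUE)
    }))
    colnames(x) <- paste0("f", seq_len(d))
    df <- tibble::as_tibble(x)
    df$label <- rep(c("A", "B", "C"), each = n_per_class)
    df$sample_id <- paste0("g", seq_len(nrow(df)))
    df
  })
}
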