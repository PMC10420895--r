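#' Default absorption band library for milk-like Vis/NIR spectra
#'
#' Gaussian bands at the wavelengths where milk constituents absorb in the
#' visible/near-infrared: water O-H first overtone and combination bands at
#' 1450 and 1940 nm (dominant), fat and fatty acids at 1210, 1790 and 2300 nm,
#' protein at 2050 and 2180 nm, lactose/lactic acid at 1194, ~1650 and
#' 2094 nm, carotenoids at 460 nm, plus a long-wavelength combination band at
#' 2498 nm. `growth` is the fractional amplitude change per unit spoilage
#' progress (0 = fresh, 1 = fully spoiled): spoilage chemistry (lactose
#' fermentation to lactic acid, water-structure and fat changes) drives the
#' 1194/1450/1790/1940/2498 nm bands up strongly, leaves protein bands nearly
#' constant and bleaches carotenoids slightly.
#'
#' @return A tibble with columns `center`, `sigma` (both nm), `amplitude`
#'   (absorbance), `growth` and `role`.
#' @export
default_band_library <- function() {
  tibble::tribble(
    ~center, ~sigma, ~amplitude, ~growth, ~role,
    460,  30, 0.12, -0.15, "carotenoids",
    1194, 22, 0.30,  1.30, "lactose/lactic acid",
    1210, 25, 0.28,  0.25, "fat",
    1450, 40, 0.90,  2.00, "water O-H 1st overtone",
    1650, 60, 0.25,  0.50, "lactose/lactic acid",
    1790, 30, 0.30,  1.50, "fat",
    1940, 45, 1.00,  1.80, "water O-H combination",
    2050, 35, 0.35,  0.08, "protein",
    2094, 25, 0.30,  0.70, "lactose/lactic acid",
    2180, 35, 0.35,  0.08, "protein",
    2300, 35, 0.40,  0.35, "fat",
    2498, 40, 0.45,  1.50, "combination band edge"
  )
}

#' Synthetic milk storage-series configuration
#'
#' Parameters of the synthetic Vis/NIR generator. Defaults emulate the study
#' design the analysis assumes: 130 samples = 13 sampling times (every 12 h
#' over 6 days of refrigerated storage) x 10 milk types, a 400-2500 nm grid at
#' 2 nm resolution, titratable acidity rising from 14.1 to 21.0 Thorner
#' degrees with a gradual phase over days 0-4 and a rapid phase from day 5,
#' and a 97/33 calibration/validation split.
#'
#' Each sample carries a latent spoilage state `tau = t + jitter`
#' (`spoilage_jitter_sd`, days): both its acidity and its band growth derive
#' from `tau`, so the class label reflects the same chemistry the spectrum
#' encodes. `acidity_noise_sd` is pure titration measurement noise on top.
#'
#' @param n_samples Total samples (default 130).
#' @param sampling_interval Hours between sampling times (default 12).
#' @param duration Storage duration in days (default 6).
#' @param wl_min,wl_max,wl_step Wavelength grid in nm (default 400-2500 by 2).
#' @param band_library Tibble as returned by [default_band_library()].
#' @param baseline_intercept,baseline_slope Linear baseline (absorbance,
#'   absorbance per nm).
#' @param acidity_start,acidity_end Acidity endpoints in Thorner degrees
#'   (14.1 at day 0, 21.0 at day 6).
#' @param acidity_drift Linear acidity drift in degrees T per day during the
#'   gradual phase.
#' @param logistic_rate,logistic_midpoint Shape of the rapid spoilage surge
#'   (per day; day of inflection).
#' @param growth_onset Acidity (degrees T) at which band growth sets in; at
#'   the default 15.0 the fresh phase is spectrally quiet, reproducing the
#'   near-zero synchronous maps of fresh milk.
#' @param growth_mix_alpha Fraction of band growth tied linearly to overall
#'   spoilage progress rather than to the post-onset surge; a small value
#'   gives fresh samples a slight systematic drift.
#' @param growth_surge_power Exponent of the post-onset surge (default 0.3):
#'   values below 1 make the surge steep at onset, the signature of
#'   log-phase microbial kinetics, so even the earliest sub-fresh samples
#'   are spectrally well separated from fresh ones.
#' @param spoilage_jitter_sd SD of the latent spoilage-state jitter in days.
#' @param acidity_noise_sd SD of titration measurement noise in degrees T.
#' @param type_amp_sd SD of the per-milk-type amplitude multiplier.
#' @param scatter_slope_sd,scatter_offset_sd Multiplicative/additive scatter
#'   artifact magnitudes (`a*x + b` with `a ~ N(1, .)`, `b ~ N(0, .)`).
#' @param noise_sd Additive absorbance noise SD per wavelength.
#' @param n_calibration,stratify Split design (97 calibration samples,
#'   stratified by class).
#' @param seed Integer seed for the whole generation.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 130, sampling_interval = 12, duration = 6,
                         wl_min = 400, wl_max = 2500, wl_step = 2,
                         band_library = default_band_library(),
                         baseline_intercept = 0.08, baseline_slope = 4e-5,
                         acidity_start = 14.1, acidity_end = 21.0,
                         acidity_drift = 0.65,
                         logistic_rate = 2, logistic_midpoint = 5,
                         growth_onset = 15.0, growth_mix_alpha = 0.1,
                         growth_surge_power = 0.3,
                         spoilage_jitter_sd = 0.15, acidity_noise_sd = 0.05,
                         type_amp_sd = 0.01,
                         scatter_slope_sd = 0.005, scatter_offset_sd = 0.002,
                         noise_sd = 1e-4,
                         n_calibration = 97, stratify = TRUE, seed = 1) {
  cfg <- list(n_samples = n_samples, sampling_interval = sampling_interval,
              duration = duration, wl_min = wl_min, wl_max = wl_max,
              wl_step = wl_step, band_library = band_library,
              baseline_intercept = baseline_intercept,
              baseline_slope = baseline_slope,
              acidity_start = acidity_start, acidity_end = acidity_end,
              acidity_drift = acidity_drift, logistic_rate = logistic_rate,
              logistic_midpoint = logistic_midpoint,
              growth_onset = growth_onset, growth_mix_alpha = growth_mix_alpha,
              growth_surge_power = growth_surge_power,
              spoilage_jitter_sd = spoilage_jitter_sd,
              acidity_noise_sd = acidity_noise_sd, type_amp_sd = type_amp_sd,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd, noise_sd = noise_sd,
              n_calibration = n_calibration, stratify = stratify, seed = seed)
  stopifnot(cfg$n_samples > 0, cfg$duration > 0, cfg$sampling_interval > 0,
            cfg$wl_step > 0, cfg$wl_min < cfg$wl_max,
            all(cfg$band_library$sigma > 0),
            all(cfg$band_library$amplitude >= 0),
            cfg$spoilage_jitter_sd >= 0, cfg$acidity_noise_sd >= 0,
            cfg$scatter_slope_sd >= 0, cfg$scatter_offset_sd >= 0,
            cfg$noise_sd >= 0, cfg$type_amp_sd >= 0)
  surge <- cfg$acidity_end - cfg$acidity_start - cfg$acidity_drift * cfg$duration
  if (surge < 0) {
    stop_lacto("acidity_drift too large: drift alone overshoots the endpoint",
               "lacto2dspec_config_error")
  }
  structure(cfg, class = "synth_config")
}

synth_grid <- function(cfg) seq(cfg$wl_min, cfg$wl_max, by = cfg$wl_step)

#' Titratable-acidity trajectory during storage
#'
#' Monotone increasing curve through the stated endpoints (14.1 degrees T at
#' day 0, 21.0 at day 6): a linear drift for the gradual phase plus a logistic
#' surge with inflection near day 5 for the rapid phase, so the mean slope on
#' days 0-4 is strictly below the mean slope on days 5-6.
#'
#' @param t Storage time in days (vectorized); must lie in
#'   `[0, cfg$duration]`.
#' @param cfg A [synth_config()].
#' @return Acidity in Thorner degrees.
#' @export
#' @examples
#' acidity_trajectory(c(0, 6), synth_config())
acidity_trajectory <- function(t, cfg = synth_config()) {
  if (any(t < 0 | t > cfg$duration)) {
    stop_lacto("storage time outside [0, duration]", "lacto2dspec_range_error")
  }
  s <- function(x) plogis(cfg$logistic_rate * (x - cfg$logistic_midpoint))
  surge <- cfg$acidity_end - cfg$acidity_start - cfg$acidity_drift * cfg$duration
  j <- surge / (s(cfg$duration) - s(0))
  cfg$acidity_start + cfg$acidity_drift * t + j * (s(t) - s(0))
}

#' Normalized spoilage progress
#'
#' The acidity trajectory rescaled to `[0, 1]`; drives band-amplitude growth.
#'
#' @inheritParams acidity_trajectory
#' @return Progress in `[0, 1]`.
#' @export
spoilage_progress <- function(t, cfg = synth_config()) {
  (acidity_trajectory(t, cfg) - cfg$acidity_start) /
    (cfg$acidity_end - cfg$acidity_start)
}

#' Band-growth driver
#'
#' The dimensionless state in `[0, 1]` that scales band-amplitude growth.
#' It blends a small linear component of overall spoilage progress
#' (`growth_mix_alpha`) with the dominant post-onset surge
#' `max(0, acidity - growth_onset) / (acidity_end - growth_onset)`. The
#' blend reproduces the observed storage phenomenology: fresh milk is
#' spectrally almost static (synchronous peaks below 1e-4), strong peaks
#' emerge within 48 h of leaving the fresh acidity range, and intensities
#' grow about four orders of magnitude by day 6, monotonically throughout.
#'
#' @inheritParams acidity_trajectory
#' @return Growth driver in `[0, 1]`.
#' @export
growth_driver <- function(t, cfg = synth_config()) {
  a <- acidity_trajectory(t, cfg)
  p <- (a - cfg$acidity_start) / (cfg$acidity_end - cfg$acidity_start)
  surge <- (pmax(0, a - cfg$growth_onset) /
              (cfg$acidity_end - cfg$growth_onset))^cfg$growth_surge_power
  cfg$growth_mix_alpha * p + (1 - cfg$growth_mix_alpha) * surge
}

#' Noise-free model spectrum at a given spoilage state
#'
#' Closed-form band sum: baseline plus Gaussian bands whose amplitudes scale
#' as `amplitude * (1 + growth * d(t))` with `d` the band-growth driver of
#' [growth_driver()]. This is the deterministic core of the generator.
#'
#' @inheritParams acidity_trajectory
#' @param type_mult Per-milk-type amplitude multiplier (default 1).
#' @return Numeric absorbance vector on the configured grid.
#' @export
clean_spectrum <- function(t, cfg = synth_config(), type_mult = 1) {
  wl <- synth_grid(cfg)
  p <- growth_driver(t, cfg)
  bands <- cfg$band_library
  amp <- bands$amplitude * (1 + bands$growth * p) * type_mult
  gauss <- exp(-outer(wl, bands$center, "-")^2 /
                 rep(2 * bands$sigma^2, each = length(wl)))
  cfg$baseline_intercept + cfg$baseline_slope * (wl - cfg$wl_min) +
    drop(gauss %*% amp)
}

#' Simulate one measured spectrum
#'
#' [clean_spectrum()] plus the measurement artifacts: multiplicative scatter
#' `a ~ N(1, scatter_slope_sd^2)`, additive offset `b ~ N(0,
#' scatter_offset_sd^2)` applied as `a*x + b`, and iid absorbance noise.
#'
#' @inheritParams clean_spectrum
#' @param seed Optional seed; two calls with the same seed return identical
#'   spectra.
#' @return A one-row `spectra_tbl`.
#' @export
simulate_spectrum <- function(t, cfg = synth_config(), type_mult = 1,
                              seed = NULL) {
  draw <- function() {
    x <- clean_spectrum(t, cfg, type_mult)
    a <- rnorm(1, 1, cfg$scatter_slope_sd)
    b <- rnorm(1, 0, cfg$scatter_offset_sd)
    a * x + b + rnorm(length(x), 0, cfg$noise_sd)
  }
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spectra_tbl(y, synth_grid(cfg), sample_id = "sim", storage_time = t * 24)
}

#' Generate a synthetic milk storage dataset
#'
#' Produces `n_samples` spectra cycling through the sampling times (every
#' `sampling_interval` hours over `duration` days) across virtual milk types.
#' Each sample gets a latent spoilage state `tau = t + jitter`; its spectrum
#' is built from `tau` and its acidity is `acidity_trajectory(tau)` plus
#' titration noise, from which the A/B/C label follows via
#' [label_from_acidity()]. A stratified 97/33 calibration/validation split is
#' assigned. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `spectra_tbl` with metadata and split filled in.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_samples = 26, wl_step = 50))
#' dplyr::count(ds, label)
generate_dataset <- function(cfg = synth_config()) {
  times_h <- seq(0, cfg$duration * 24, by = cfg$sampling_interval)
  n_times <- length(times_h)
  n_types <- ceiling(cfg$n_samples / n_times)
  withr::with_seed(cfg$seed, {
    type_mult <- rnorm(n_types, 1, cfg$type_amp_sd)
    i <- seq_len(cfg$n_samples)
    t_days <- times_h[(i - 1) %% n_times + 1] / 24
    type <- (i - 1) %/% n_times + 1
    tau <- pmin(pmax(t_days + rnorm(cfg$n_samples, 0, cfg$spoilage_jitter_sd), 0),
                cfg$duration)
    acidity <- acidity_trajectory(tau, cfg) +
      rnorm(cfg$n_samples, 0, cfg$acidity_noise_sd)
    # floor at the lower edge of the labelling scheme, 2 d.p. as titrated
    acidity <- round(pmax(acidity, 13), 2)
    x <- vapply(i, function(k) {
      a <- rnorm(1, 1, cfg$scatter_slope_sd)
      b <- rnorm(1, 0, cfg$scatter_offset_sd)
      y <- clean_spectrum(tau[k], cfg, type_mult[type[k]])
      a * y + b + rnorm(length(y), 0, cfg$noise_sd)
    }, numeric(length(synth_grid(cfg))))
    ds <- spectra_tbl(t(x), synth_grid(cfg),
                      sample_id = sprintf("S%03d", i),
                      storage_time = t_days * 24,
                      acidity = acidity,
                      label = label_from_acidity(acidity))
    split_dataset(ds, n_calibration = cfg$n_calibration,
                  seed = derive_seed(cfg$seed, "split"),
                  stratify = cfg$stratify)
  })
}
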