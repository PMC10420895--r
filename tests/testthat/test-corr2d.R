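test_that("reference spectrum is the pointwise mean of fresh spectra", {
  ds <- generate_dataset(small_config())
  fresh <- ds[ds$label == "A", ]
  ref <- reference_spectrum(ds)
  # brute-force loop oracle
  acc <- rep(0, length(spec_wavelengths(ds)))
  for (i in seq_len(nrow(fresh))) acc <- acc + as.numeric(spectra_matrix(fresh)[i, ])
  expect_equal(drop(spectra_matrix(ref)), acc / nrow(fresh),
               tolerance = 1e-12, ignore_attr = TRUE)
  one <- ds[1, ]
  expect_equal(spectra_matrix(reference_spectrum(one, label = NULL)),
               spectra_matrix(one), tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(reference_spectrum(ds, label = "Z"),
               class = "lacto2dspec_input_error")
})

test_that("dynamic spectra are pointwise deviations", {
  x <- c(1, 2, 3, 4)
  r <- c(0.5, 1, 1.5, 6)
  ds <- tiny_spectra(x)
  expect_equal(drop(spectra_matrix(dynamic_spectra(ds, r))), x - r,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(drop(spectra_matrix(dynamic_spectra(ds, x))), rep(0, 4),
               ignore_attr = TRUE)
  expect_error(dynamic_spectra(ds, c(1, 2)), class = "lacto2dspec_grid_error")
})

test_that("single-sample synchronous map is the outer product of the dynamic spectrum", {
  m <- sync_single(c(2, 3), c(1, 1))
  expect_equal(unclass(m), rbind(c(1, 2), c(2, 4)), ignore_attr = TRUE)
  # spectrum equal to the reference gives the zero matrix
  r <- runif(8)
  m0 <- sync_single(tiny_spectra(r), r)
  expect_true(all(m0 == 0))
  # random spectra against a double-loop oracle
  withr::with_seed(11, {
    for (k in 1:5) {
      x <- runif(10)
      r <- runif(10)
      m <- unclass(sync_single(tiny_spectra(x), r))
      oracle <- matrix(0, 10, 10)
      for (i in 1:10) for (j in 1:10) oracle[i, j] <- (x[i] - r[i]) * (x[j] - r[j])
      expect_equal(m, oracle, tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("ensemble synchronous map matches the Noda estimator loop oracle", {
  withr::with_seed(2, {
    g <- matrix(runif(40), 5, 8)
    r <- runif(8)
  })
  ds <- spectra_tbl(g, seq_len(8))
  m <- unclass(sync_ensemble(ds, r))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    for (s in 1:5) oracle[i, j] <- oracle[i, j] + (g[s, i] - r[i]) * (g[s, j] - r[j])
  }
  oracle <- oracle / 4
  expect_equal(m, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # orthogonal dynamic pair with m - 1 = 1 gives the identity
  ds2 <- spectra_tbl(rbind(c(1, 0), c(0, 1)), c(1, 2))
  expect_equal(unclass(sync_ensemble(ds2, c(0, 0))), diag(2),
               ignore_attr = TRUE)
  expect_error(sync_ensemble(ds2[1, ], c(0, 0)),
               class = "lacto2dspec_input_error")
})

test_that("synchronous maps are symmetric PSD with nonnegative diagonal", {
  withr::with_seed(9, {
    for (k in 1:100) {
      n <- sample(5:12, 1)
      m_rows <- sample(2:6, 1)
      ds <- spectra_tbl(matrix(runif(m_rows * n), m_rows, n), seq_len(n))
      r <- runif(n)
      m <- unclass(sync_ensemble(ds, r))
      expect_equal(m, t(m), tolerance = 1e-12)
      expect_true(all(diag(m) >= 0))
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1e-10 * max(abs(ev), 1)))
    }
  })
})

test_that("singleton ensemble equals the single-sample map up to normalization", {
  # documented m - 1 vs 1 normalization: compare on a 2-member group of
  # identical spectra, where the ensemble average equals the common outer
  # product
  x <- runif(6)
  r <- runif(6)
  ds <- spectra_tbl(rbind(x, x), seq_len(6))
  m_ens <- unclass(sync_ensemble(ds, r))
  m_one <- unclass(sync_single(tiny_spectra(x, seq_len(6)), r))
  expect_equal(m_ens, 2 * m_one, tolerance = 1e-12)
})

test_that("asynchronous map uses the Hilbert-Noda matrix and is antisymmetric", {
  withr::with_seed(4, {
    g <- matrix(runif(24), 4, 6)
    r <- runif(6)
  })
  ds <- spectra_tbl(g, seq_len(6))
  psi <- unclass(async_ensemble(ds, r))
  d <- sweep(g, 2, r)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    for (s in 1:4) for (k in 1:4) {
      njk <- if (s == k) 0 else 1 / (pi * (k - s))
      oracle[i, j] <- oracle[i, j] + d[s, i] * njk * d[k, j]
    }
  }
  oracle <- oracle / 3
  expect_equal(psi, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(psi, -t(psi), tolerance = 1e-12)
  expect_equal(diag(psi), rep(0, 6), tolerance = 1e-12, ignore_attr = TRUE)
  # identical dynamic spectra give the zero matrix
  same <- spectra_tbl(rbind(g[1, ], g[1, ], g[1, ]), seq_len(6))
  expect_equal(max(abs(unclass(async_ensemble(same, r)))), 0, tolerance = 1e-12)
  expect_error(async_ensemble(ds[1:2, ], r), class = "lacto2dspec_input_error")
})

test_that("autocorrelation is the matrix diagonal and the squared dynamic spectrum", {
  m <- sync_single(c(2, 3), c(1, 1))
  expect_equal(autocorrelation(m)$intensity, c(1, 4))
  withr::with_seed(6, x <- runif(12))
  r <- runif(12)
  ac <- autocorrelation(sync_single(tiny_spectra(x, 1:12), r))
  expect_equal(ac$intensity, (x - r)^2, tolerance = 1e-12)
  feats <- autocorr_features(tiny_spectra(x, 1:12), r)
  expect_equal(drop(spectra_matrix(feats)), (x - r)^2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("peak lookup snaps to the nearest grid point, ties toward lower", {
  wl <- seq(400, 2500, by = 2)
  v <- seq_along(wl) / length(wl)
  m <- sync_single(tiny_spectra(v, wl), rep(0, length(wl)))
  expect_equal(peak_value(m, 1450, 1940), peak_value(m, 1940, 1450))
  i1450 <- which(wl == 1450)
  expect_equal(peak_value(m, 1450, 1450), v[i1450]^2)
  # 1451 on a 2 nm grid is equidistant between 1450 and 1452: lower wins
  expect_equal(peak_value(m, 1451, 1451), v[i1450]^2)
  expect_error(peak_value(m, 300, 1450), class = "lacto2dspec_range_error")
})

test_that("autocorrelation peaks grow monotonically with storage day", {
  cfg <- small_config(noise_sd = 0, scatter_slope_sd = 0,
                      scatter_offset_sd = 0, spoilage_jitter_sd = 0,
                      acidity_noise_sd = 0)
  wl <- seq(cfg$wl_min, cfg$wl_max, by = cfg$wl_step)
  ref <- clean_spectrum(0, cfg)
  for (peak in c(1194, 1450, 1790, 1940)) {
    vals <- vapply(0:6, function(day) {
      m <- sync_single(spectra_tbl(clean_spectrum(day, cfg), wl), ref)
      peak_value(m, peak, peak)
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})
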