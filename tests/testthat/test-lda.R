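test_that("scatter matrices match the definition's double-loop oracle", {
  x <- rbind(c(1, 2), c(2, 1), c(3, 3), c(7, 8), c(8, 7), c(9, 9))
  y <- c("A", "A", "A", "B", "B", "B")
  sc <- scatter_matrices(x, y)
  n <- nrow(x)
  classes <- unique(y)
  grand <- colMeans(x)
  sb <- matrix(0, 2, 2)
  sw <- matrix(0, 2, 2)
  for (cl in classes) {
    xi <- x[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    sb <- sb + nrow(xi) * tcrossprod(mi - grand)
    for (j in seq_len(nrow(xi))) sw <- sw + tcrossprod(xi[j, ] - mi)
  }
  expect_equal(sc$S_B, sb / n, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sc$S_W, sw / n, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scatter matrices honour their structural limits", {
  # all class means equal: between-class scatter vanishes
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  sc <- scatter_matrices(x, c("A", "A", "B", "B"))
  expect_equal(max(abs(sc$S_B)), 0, tolerance = 1e-12)
  # every sample at its class mean: within-class scatter vanishes
  x2 <- rbind(c(1, 1), c(1, 1), c(5, 5), c(5, 5))
  sc2 <- scatter_matrices(x2, c("A", "A", "B", "B"))
  expect_equal(max(abs(sc2$S_W)), 0, tolerance = 1e-12)
  expect_warning(scatter_matrices(x, rep("A", 4)), "single class")
})

test_that("between plus within scatter equals total scatter", {
  withr::with_seed(13, {
    for (k in 1:10) {
      x <- matrix(rnorm(60), 20, 3)
      y <- sample(c("A", "B", "C"), 20, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
      if (length(unique(y)) < 2) next
      sc <- scatter_matrices(x, y)
      total <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
      expect_equal(sc$S_B + sc$S_W, total, tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(sc$S_B, t(sc$S_B), tolerance = 1e-12)
      expect_equal(sc$S_W, t(sc$S_W), tolerance = 1e-12)
    }
  })
})

test_that("two separated 1D classes give the only possible direction", {
  withr::with_seed(3, {
    df <- tibble::tibble(f1 = c(rnorm(15, 0, 1), rnorm(15, 5, 1)),
                         label = rep(c("A", "B"), each = 15))
  })
  m <- fit_lda(df, m = 1)
  expect_equal(abs(drop(m$V)), 1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("LDA recovers a known separating direction", {
  withr::with_seed(21, {
    n <- 60
    x <- matrix(rnorm(3 * n * 4), 3 * n, 4)
    x[, 1] <- x[, 1] + rep(c(0, 8, 16), each = n)
    df <- tibble::as_tibble(x, .name_repair = ~paste0("f", 1:4))
    df$label <- rep(c("A", "B", "C"), each = n)
  })
  m <- fit_lda(df)
  lead <- m$V[, 1] / sqrt(sum(m$V[, 1]^2))
  expect_gt(abs(lead[1]), 0.99)
})

test_that("fitted trace ratio beats random projections of the same rank", {
  blobs <- gaussian_blobs(n_per_class = 15, d = 5, sep = 4)
  x <- as.matrix(blobs[paste0("f", 1:5)])
  y <- blobs$label
  sc <- scatter_matrices(x, y)
  m <- fit_lda(blobs, m = 2)
  fitted_tr <- trace_ratio(m$V, sc$S_B, sc$S_W)
  expect_equal(fitted_tr, m$trace_ratio, tolerance = 1e-8)
  withr::with_seed(99, {
    random_tr <- replicate(1000, {
      v <- qr.Q(qr(matrix(rnorm(10), 5, 2))) # random orthonormal basis
      trace_ratio(v, sc$S_B, sc$S_W)
    })
  })
  expect_true(all(fitted_tr >= random_tr))
})

test_that("trace ratio is invariant to positive rescaling of the projection", {
  blobs <- gaussian_blobs(n_per_class = 10)
  x <- as.matrix(blobs[paste0("f", 1:4)])
  sc <- scatter_matrices(x, blobs$label)
  m <- fit_lda(blobs)
  expect_equal(trace_ratio(m$V, sc$S_B, sc$S_W),
               trace_ratio(2.5 * m$V, sc$S_B, sc$S_W), tolerance = 1e-8)
})

test_that("well-separated Gaussian classes are recovered at 99%+", {
  for (s in 1:5) {
    blobs <- gaussian_blobs(n_per_class = 67, d = 6, sep = 6, seed = 100 + s)
    m <- fit_lda(blobs)
    pred <- predict(m, blobs)$.pred
    expect_gte(mean(pred == blobs$label), 0.99)
  }
})

test_that("classification is by nearest projected centroid with A<B<C ties", {
  blobs <- gaussian_blobs()
  m <- fit_lda(blobs)
  # a point exactly at a projected centroid gets that class
  x <- as.matrix(blobs[paste0("f", 1:4)])
  cm <- colMeans(x[blobs$label == "B", ])
  expect_identical(predict(m, rbind(cm))$.pred, "B")
  # force an exact tie: duplicate centroids in a symmetric 2-class problem
  df <- tibble::tibble(f1 = c(-1, -1, 1, 1), f2 = c(0.5, -0.5, 0.5, -0.5),
                       label = c("A", "A", "B", "B"))
  m2 <- fit_lda(df, m = 1)
  midpoint <- rbind(c(0, 0))
  colnames(midpoint) <- c("f1", "f2")
  expect_identical(predict(m2, midpoint)$.pred, "A")
})

test_that("PCA-then-LDA route agrees with ridge route on well-posed data", {
  blobs <- gaussian_blobs(n_per_class = 30)
  m1 <- fit_lda(blobs, method = "ridge")
  m2 <- fit_lda(blobs, method = "pca")
  p1 <- predict(m1, blobs)$.pred
  p2 <- predict(m2, blobs)$.pred
  expect_gt(mean(p1 == p2), 0.97)
})

test_that("leading discriminant direction agrees with an established 2-class solver", {
  skip_if_not_installed("MASS")
  withr::with_seed(17, {
    x <- matrix(rnorm(200), 50, 4)
    x[26:50, ] <- x[26:50, ] + matrix(c(2, 1, 0, -1), 25, 4, byrow = TRUE)
    y <- rep(c("A", "B"), each = 25)
  })
  df <- tibble::as_tibble(x, .name_repair = ~paste0("f", 1:4))
  df$label <- y
  ours <- fit_lda(df, m = 1, ridge = 0)$V[, 1]
  theirs <- MASS::lda(x, y)$scaling[, 1]
  cos_angle <- abs(sum(ours * theirs)) /
    sqrt(sum(ours^2) * sum(theirs^2))
  expect_gt(cos_angle, 0.999)
})

test_that("high-dimensional spectra need the ridge and fit cleanly", {
  ds <- generate_dataset(small_config())
  cal <- calibration(ds)
  m <- fit_lda(cal)
  expect_equal(ncol(m$V), 2)
  expect_gt(m$ridge, 0)
  acc <- mean(predict(m, cal)$.pred == cal$label)
  expect_gt(acc, 0.9)
  expect_error(fit_lda(cal, m = 5), class = "lacto2dspec_config_error")
})
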