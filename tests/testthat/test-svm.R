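test_that("kernel formulas evaluate in closed form", {
  expect_equal(kernel_eval(svm_config("linear"), c(1, 2), c(3, 4)), 11)
  x <- c(0.3, -0.7, 1.1)
  expect_equal(kernel_eval(svm_config("rbf", gamma = 2.5), x, x), 1)
  # value from the published optimum G = 3.59, checked against a
  # hand-evaluated exponential
  a <- c(0.1, 0.2)
  b <- c(0.4, 0.0)
  expect_equal(kernel_eval(svm_config("rbf", gamma = 3.59), a, b),
               exp(-3.59 * (0.3^2 + 0.2^2)), tolerance = 1e-12)
  expect_equal(kernel_eval(svm_config("polynomial", gamma = 0.5, coef0 = 1,
                                      degree = 3), c(1, 1), c(2, 2)),
               (0.5 * 4 + 1)^3, tolerance = 1e-12)
  expect_equal(kernel_eval(svm_config("sigmoid", gamma = 0.1, coef0 = -0.2),
                           c(1, 2), c(3, 4)), tanh(0.1 * 11 - 0.2),
               tolerance = 1e-12)
  cfg <- svm_config("rbf", gamma = 1)
  cfg$gamma <- NULL
  expect_error(kernel_eval(cfg, a, b), class = "lacto2dspec_config_error")
})

test_that("rbf Gram matrices are symmetric positive semidefinite", {
  withr::with_seed(31, {
    x <- matrix(rnorm(40), 10, 4)
  })
  cfg <- svm_config("rbf", gamma = 0.7)
  gram <- outer(seq_len(10), seq_len(10),
                Vectorize(function(i, j) kernel_eval(cfg, x[i, ], x[j, ])))
  expect_equal(gram, t(gram), tolerance = 1e-12)
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})

test_that("separable and XOR problems train to 100%", {
  # linearly separable, large cost
  df <- tibble::tibble(f1 = c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)),
                       f2 = rnorm(40, 0, 0.3),
                       label = rep(c("A", "B"), each = 20))
  m <- train_svm(df, svm_config("linear", cost = 1000))
  expect_true(all(predict(m, df)$.pred == df$label))
  expect_gte(m$support_count, 2)
  # the classic XOR arrangement needs a nonlinear kernel
  xor <- tibble::tibble(f1 = c(0, 1, 0, 1), f2 = c(0, 0, 1, 1),
                        label = c("A", "B", "B", "A"))
  mx <- train_svm(xor, svm_config("rbf", cost = 100, gamma = 2))
  expect_true(all(predict(mx, xor)$.pred == xor$label))
})

test_that("training and prediction are deterministic", {
  blobs <- gaussian_blobs(n_per_class = 15)
  probe <- gaussian_blobs(n_per_class = 5, seed = 7)
  cfg <- svm_config("rbf", cost = 4, gamma = 0.3)
  m1 <- train_svm(blobs, cfg)
  m2 <- train_svm(blobs, cfg)
  expect_identical(predict(m1, probe)$.pred, predict(m2, probe)$.pred)
  expect_identical(m1$support_count, m2$support_count)
})

test_that("one-vs-one reconstruction matches the reference predictor", {
  # the package's own kernel-voting predictor (used for JSON round trips)
  # must reproduce the in-memory libsvm predictions exactly
  for (kern in c("linear", "rbf", "polynomial", "sigmoid")) {
    blobs <- gaussian_blobs(n_per_class = 12, sep = 4)
    probe <- gaussian_blobs(n_per_class = 8, sep = 4, seed = 8)
    cfg <- svm_config(kern, cost = 10, gamma = 0.4, coef0 = 0.5)
    m <- train_svm(blobs, cfg)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    expect_null(m2$fit)
    expect_identical(predict(m2, probe)$.pred, predict(m, probe)$.pred)
  }
})

test_that("cross-validation is stratified, deterministic and correct on easy data", {
  blobs <- gaussian_blobs(n_per_class = 20, sep = 8)
  cfg <- svm_config("rbf", cost = 10, gamma = 0.2, seed = 3)
  a1 <- cross_val_accuracy(blobs, cfg)
  a2 <- cross_val_accuracy(blobs, cfg)
  expect_identical(a1, a2)
  expect_equal(a1, 1.0)
  cfg2 <- cfg
  cfg2$seed <- 4
  expect_true(is.numeric(cross_val_accuracy(blobs, cfg2)))
  small <- blobs[c(1:3, 21:23, 41:43), ]
  expect_error(cross_val_accuracy(small, cfg),
               class = "lacto2dspec_cv_error")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  accs <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      df <- tibble::tibble(f1 = rnorm(60), f2 = rnorm(60),
                           label = sample(rep(c("A", "B", "C"), 20)))
    })
    cross_val_accuracy(df, svm_config("rbf", cost = 1, gamma = 0.5,
                                      seed = s))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.1)
})

test_that("grid search is exhaustive with ties broken toward smaller C then G", {
  blobs <- gaussian_blobs(n_per_class = 10, sep = 8)
  gs <- grid_search(blobs, svm_config("rbf", seed = 2),
                    log2_cost = c(0, 2, 4), log2_gamma = c(-3, -1))
  expect_equal(nrow(gs$surface), 6)
  expect_equal(nrow(dplyr::distinct(gs$surface[c("log2_cost", "log2_gamma")])), 6)
  # separable data: many grid points reach accuracy 1; smallest C then G wins
  top <- max(gs$surface$accuracy)
  tied <- gs$surface[gs$surface$accuracy == top, ]
  expect_equal(gs$best$log2_cost, min(tied$log2_cost))
  expect_equal(gs$best$log2_gamma,
               min(tied$log2_gamma[tied$log2_cost == gs$best$log2_cost]))
  # 1x1 grid returns that point
  g1 <- grid_search(blobs, svm_config("rbf", seed = 2),
                    log2_cost = 3, log2_gamma = -2)
  expect_equal(g1$best$log2_cost, 3)
  expect_equal(g1$best$log2_gamma, -2)
})

test_that("PSO global best is monotone, deterministic and finds a unimodal optimum", {
  # smooth unimodal surface standing in for a CV-accuracy landscape
  fn <- function(p) exp(-((p[1] - 3.2)^2 + (p[2] + 7.4)^2) / 40)
  cfg <- pso_config(swarm = 15, iterations = 40, lower = c(-5, -15),
                    upper = c(15, 3), seed = 5)
  res <- pso_maximize(fn, cfg)
  expect_true(all(diff(res$trace) >= 0))
  res2 <- pso_maximize(fn, cfg)
  expect_identical(res$par, res2$par)
  # dense-grid oracle: PSO lands within one coarse grid step (2 in log2)
  grid <- expand.grid(c1 = seq(-5, 15, by = 0.25), c2 = seq(-15, 3, by = 0.25))
  vals <- apply(grid, 1, fn)
  opt <- unlist(grid[which.max(vals), ])
  expect_lt(max(abs(res$par - opt)), 2)
  # bounds are respected
  expect_true(all(res$par >= cfg$lower & res$par <= cfg$upper))
})

test_that("PSO handles constant objectives and degenerate bounds", {
  cfg <- pso_config(swarm = 5, iterations = 5, lower = c(0, 0),
                    upper = c(1, 1), seed = 1)
  res <- pso_maximize(function(p) 0.5, cfg)
  expect_equal(res$value, 0.5)
  expect_true(all(res$par >= 0 & res$par <= 1))
  dg <- pso_config(swarm = 5, iterations = 5, lower = c(2, 3),
                   upper = c(2, 3), seed = 1)
  expect_warning(res2 <- pso_maximize(function(p) sum(p), dg), "degenerate")
  expect_equal(res2$par, c(2, 3))
})

test_that("pso_optimize tunes [C, G] over cross-validated accuracy", {
  blobs <- gaussian_blobs(n_per_class = 10, sep = 5)
  res <- pso_optimize(blobs, svm_config("rbf", seed = 2),
                      pso_config(swarm = 6, iterations = 8, seed = 3))
  expect_s3_class(res$config, "svm_config")
  expect_equal(res$cost, res$config$cost)
  expect_true(all(diff(res$trace) >= 0))
  expect_gte(res$accuracy, 0.9)
})

test_that("training accuracy rises with C while CV accuracy peaks interior", {
  # overfitting/underfitting trend over a C sweep at fixed gamma
  withr::with_seed(55, {
    n <- 40
    x1 <- rnorm(n)
    df <- tibble::tibble(f1 = c(x1 - 0.8, x1 + 0.8),
                         f2 = rnorm(2 * n),
                         label = rep(c("A", "B"), each = n))
  })
  costs <- 2^seq(-7, 9, by = 2)
  train_acc <- numeric(length(costs))
  cv_acc <- numeric(length(costs))
  for (i in seq_along(costs)) {
    cfg <- svm_config("rbf", cost = costs[i], gamma = 2, seed = 6)
    m <- train_svm(df, cfg)
    train_acc[i] <- mean(predict(m, df)$.pred == df$label)
    cv_acc[i] <- cross_val_accuracy(df, cfg)
  }
  # monotone trend allowing small plateaus: fit direction via correlation
  expect_gt(cor(seq_along(costs), train_acc, method = "spearman"), 0.8)
  expect_gt(max(head(cv_acc, -2)[-1]), cv_acc[length(cv_acc)] - 1e-9)
  expect_gte(max(cv_acc) - cv_acc[length(cv_acc)], 0)
})
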