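test_that("PLSR at full rank reproduces ordinary least squares", {
  for (sd in 1:3) {
    set.seed(sd)
    X <- matrix(rnorm(20 * 5), 20)
    y <- as.numeric(X %*% rnorm(5) + rnorm(1) + 0.01 * rnorm(20))
    fit <- nircal:::pls_core(X, y, 5)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(fit$coef[, 5], ols[-1], tolerance = 1e-6)
    expect_equal(fit$intercept[5], ols[1], tolerance = 1e-6)
  }
})

test_that("an exact two-predictor linear response is fit perfectly", {
  set.seed(14)
  X <- matrix(rnorm(30 * 2), 30)
  y <- as.numeric(3 * X[, 1] - X[, 2])
  m <- fit_plsr(X, y, max_lv = 2, n_folds = 5, seed = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("rmsecv detects a perfectly learnable response", {
  set.seed(15)
  X <- matrix(rnorm(20 * 5), 20)
  y <- 2 * X[, 1]
  cv <- rmsecv(X, y, n_folds = 5, max_lv = 5, seed = 3)
  expect_lt(cv$best_rmsecv, 1e-8)
})

test_that("rmsecv of a permuted response is near the response sd", {
  set.seed(5)
  X <- matrix(rnorm(60 * 10), 60)
  y <- sample(rnorm(60, sd = 2))
  cv <- rmsecv(X, y, n_folds = 6, max_lv = 5, seed = 5)
  expect_gt(cv$best_rmsecv, 0.5 * sd(y))
  expect_lt(cv$best_rmsecv, 1.5 * sd(y))
})

test_that("rmsecv is deterministic under its seed and guards its inputs", {
  set.seed(16)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rnorm(40)
  expect_identical(rmsecv(X, y, 5, 4, seed = 9), rmsecv(X, y, 5, 4, seed = 9))
  expect_error(rmsecv(X[1:3, ], y[1:3], n_folds = 5, max_lv = 2, seed = 1),
               "folds")
})

test_that("the latent-variable count is capped and ties go to the smaller count", {
  set.seed(17)
  X <- matrix(rnorm(50 * 30), 50)
  y <- as.numeric(X %*% c(rep(1, 3), rep(0, 27))) + rnorm(50, sd = 0.1)
  m <- fit_plsr(X, y, max_lv = 10, n_folds = 10, seed = 2)
  expect_lte(m$n_latent_variables, 10L)
  expect_identical(m$n_latent_variables,
                   as.integer(which.min(m$cv$rmsecv_by_lv)))
})

test_that("PLSR predictions are batch-invariant and slice full-grid input", {
  set.seed(18)
  X <- matrix(rnorm(25 * 8), 25)
  y <- as.numeric(X %*% rnorm(8)) + rnorm(25, sd = 0.05)
  sub <- c(2L, 5L, 7L)
  m <- fit_plsr(X[, sub], y, max_lv = 3, n_folds = 5, seed = 4,
                subset = sub, n_full = 8L)
  batch <- predict(m, X[, sub])
  expect_equal(predict(m, X[1, sub, drop = FALSE]), batch[1])
  expect_equal(predict(m, X), batch)       # full grid sliced internally
  expect_error(predict(m, X[, 1:5]), "columns")
  # centered input reduces prediction to a pure dot product + y mean
  Xc <- sweep(X[, sub], 2, colMeans(X[, sub]))
  expect_equal(predict(m, Xc + rep(colMeans(X[, sub]), each = 25)), batch)
  expect_equal(as.numeric(Xc %*% m$coefficients) +
                 (m$intercept + sum(colMeans(X[, sub]) * m$coefficients)),
               batch)
})

test_that("PLSR predictions are invariant to wavelength column order", {
  set.seed(19)
  X <- matrix(rnorm(30 * 6), 30)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(30, sd = 0.1)
  perm <- sample(6)
  m1 <- fit_plsr(X, y, max_lv = 4, n_folds = 5, seed = 6)
  m2 <- fit_plsr(X[, perm], y, max_lv = 4, n_folds = 5, seed = 6)
  expect_equal(predict(m2, X[, perm]), predict(m1, X), tolerance = 1e-10)
})
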