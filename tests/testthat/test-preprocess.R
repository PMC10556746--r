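test_that("snv centers and scales rows with the sample (n-1) sd", {
  expect_equal(unname(snv(matrix(c(1, 2, 3), 1))[1, ]), c(-1, 0, 1))
  expect_error(snv(matrix(5, 1, 3, dimnames = list("S9", NULL))), "S9")
  set.seed(4)
  X <- matrix(rnorm(20 * 50), 20)
  out <- snv(X)
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))
})

test_that("msc inverts affine scatter against the reference", {
  set.seed(5)
  ref <- runif(30)
  X <- rbind(3 + 2 * ref, ref)
  out <- msc(X, reference = ref)
  expect_equal(unname(out[1, ]), ref, tolerance = 1e-12)
  expect_equal(unname(out[2, ]), ref, tolerance = 1e-12)  # identity row
  expect_error(msc(matrix(1:3, 3, 1)), "2 wavelengths", fixed = FALSE)
})

test_that("msc equalizes scatter-only replicates of one concentration", {
  # all samples share (numerically) one concentration; only m and a differ
  cfg <- default_milk_powder_config("GOS", n_points = 150, n_samples = 10,
                                    conc_range = c(10, 10 + 1e-9),
                                    tilt = c(0, 0), matrix_jitter = 0,
                                    noise_sd = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  out <- msc(sim$spectra$absorbance)
  for (i in 2:10) {
    expect_equal(unname(out[i, ]), unname(out[1, ]), tolerance = 1e-9)
  }
})

test_that("min-max normalization maps every row onto [0, 1]", {
  expect_equal(unname(normalize_minmax(matrix(c(2, 4, 6), 1))[1, ]),
               c(0, 0.5, 1))
  row01 <- matrix(c(0, 0.25, 1), 1)
  expect_equal(normalize_minmax(row01), row01)  # idempotent on canonical rows
  expect_error(normalize_minmax(matrix(1, 2, 4)), "constant")
  set.seed(6)
  X <- matrix(rnorm(15 * 40), 15)
  out <- normalize_minmax(X)
  expect_equal(unname(apply(out, 1, min)), rep(0, 15))
  expect_equal(unname(apply(out, 1, max)), rep(1, 15))
})

test_that("savitzky_golay reproduces polynomials up to its order", {
  X <- matrix(7, 3, 30)
  expect_equal(savitzky_golay(X, 11, 2), X)  # constants, any window
  x <- seq(-2, 2, length.out = 41)
  quad <- matrix(3 + 0.5 * x - 1.2 * x^2, 1)
  expect_equal(savitzky_golay(quad, 9, 2), quad, tolerance = 1e-10)
  expect_error(savitzky_golay(quad, 8, 2), "odd")
  expect_error(savitzky_golay(quad, 43, 2), "ncol")
})

test_that("interior SG weights match the least-squares oracle (-3,12,17,12,-3)/35", {
  # oracle: hat matrix row of the local quadratic fit on offsets -2..2
  A <- outer(-2:2, 0:2, `^`)
  H <- A %*% solve(crossprod(A)) %*% t(A)
  expect_equal(H[3, ], c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(25)
  sm <- savitzky_golay(matrix(x, 1), 5, 2)[1, ]
  for (j in 5:20) {
    expect_equal(sm[j], sum(H[3, ] * x[(j - 2):(j + 2)]), tolerance = 1e-10)
  }
})

test_that("row-local methods commute with row permutation and keep shape", {
  set.seed(9)
  X <- matrix(rnorm(12 * 25), 12)
  perm <- sample(12)
  for (f in list(snv, normalize_minmax,
                 function(m) savitzky_golay(m, 7, 2))) {
    expect_identical(dim(f(X)), dim(X))
    expect_equal(f(X[perm, ]), f(X)[perm, ])
  }
})

test_that("savitzky_golay is linear in its input", {
  set.seed(10)
  X <- matrix(rnorm(100), 4)
  Y <- matrix(rnorm(100), 4)
  expect_equal(savitzky_golay(2 * X - 3 * Y, 7, 3),
               2 * savitzky_golay(X, 7, 3) - 3 * savitzky_golay(Y, 7, 3),
               tolerance = 1e-10)
})

test_that("fitted preprocessor freezes the MSC reference on calibration rows", {
  set.seed(11)
  Xc <- matrix(rnorm(8 * 20, mean = 1), 8)
  Xp <- matrix(rnorm(4 * 20, mean = 1), 4)
  pp <- fit_preprocessor("msc", Xc)
  expect_equal(pp$state$reference, colMeans(Xc))
  # prediction rows are corrected against the calibration mean, not their own
  expect_equal(apply_preprocessor(pp, Xp), msc(Xp, reference = colMeans(Xc)))
  expect_false(isTRUE(all.equal(apply_preprocessor(pp, Xp), msc(Xp))))
  # stateless methods pass through their plain counterparts
  expect_equal(apply_preprocessor(fit_preprocessor("snv", Xc), Xp), snv(Xp))
  expect_identical(apply_preprocessor(fit_preprocessor("none", Xc), Xp), Xp)
})
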