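test_that("EDF schedule satisfies its boundary conditions and decreases", {
  expect_equal(edf_ratio(1, 40, 1557), 1)
  expect_equal(edf_ratio(40, 40, 1557), 2 / 1557)
  expect_equal(edf_ratio(100, 100, 100), 0.02)
  r <- edf_ratio(1:40, 40, 1557)
  expect_true(all(diff(r) < 0))
  expect_error(edf_ratio(1, 40, 2), "p < 3")
  expect_error(edf_ratio(0, 40, 100), "out of range")
})

test_that("ars_sample concentrates on the weighted support", {
  expect_identical(ars_sample(c(1, 0, 0), 5, seed = 1), 1L)
  expect_error(ars_sample(c(0, 0), 3, seed = 1), "zero")
  expect_error(ars_sample(c(-1, 2), 3, seed = 1), "non-negative")
  # uniform weights, many draws: the whole support appears
  expect_identical(ars_sample(rep(1, 6), 5000, seed = 2), 1:6)
})

test_that("ars_sample draws indices at their weight frequency", {
  n_rep <- 40000L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    hits <- hits + (ars_sample(c(3, 1), 1, seed = i)[1] == 1L)
  }
  # P(index 1) = 0.75; band of +-1% as an absolute frequency
  expect_lt(abs(hits / n_rep - 0.75), 0.01)
})

test_that("CARS recovers a single informative predictor", {
  set.seed(20)
  X <- matrix(rnorm(50 * 30), 50)
  j <- 17L
  y <- as.numeric(1.5 * X[, j])
  sel <- cars_select(X, y, cars_params(n_mc_runs = 20, max_lv = 5,
                                       n_folds = 5, seed = 2))
  expect_true(j %in% sel$selected_indices)
})

test_that("CARS diagnostics follow the run schedule and are deterministic", {
  sim <- simulate_dataset(informative_fixture_config(n_samples = 40))
  X <- sim$spectra$absorbance
  y <- unname(sim$reference$values)
  p <- cars_params(n_mc_runs = 15, n_folds = 5, seed = 7)
  a <- cars_select(X, y, p)
  b <- cars_select(X, y, p)
  expect_identical(a$selected_indices, b$selected_indices)
  expect_identical(a$diagnostics$rmsecv_trace, b$diagnostics$rmsecv_trace)
  expect_length(a$diagnostics$rmsecv_trace, 15L)
  # enforced-retention schedule (ceiling of EDF * p) is non-increasing
  sched <- ceiling(edf_ratio(1:15, 15, ncol(X)) * ncol(X))
  expect_true(all(diff(sched) <= 0))
  # the winning subset is the argmin run's subset
  br <- a$diagnostics$best_run
  expect_identical(br, which.min(a$diagnostics$rmsecv_trace))
  expect_identical(a$selected_indices, sort(a$diagnostics$subsets[[br]]))
  expect_true(all(a$selected_indices >= 1 & a$selected_indices <= ncol(X)))
})

test_that("random frog returns the requested count with valid probabilities", {
  sim <- simulate_dataset(informative_fixture_config(n_samples = 40))
  X <- sim$spectra$absorbance
  y <- unname(sim$reference$values)
  pr <- frog_params(n_iterations = 300, n_selected = 12, n_folds = 4,
                    seed = 3)
  a <- random_frog_select(X, y, pr)
  expect_length(a$selected_indices, 12L)
  prob <- a$diagnostics$probability
  expect_length(prob, ncol(X))
  expect_true(all(prob >= 0 & prob <= 1))
  expect_identical(a$selected_indices,
                   random_frog_select(X, y, pr)$selected_indices)
  expect_error(random_frog_select(X, y, frog_params(n_selected = 500)),
               "exceeds")
})

test_that("a hill-climbing frog never leaves an optimal starting subset", {
  sim <- simulate_dataset(informative_fixture_config(n_samples = 40))
  X <- sim$spectra$absorbance
  y <- unname(sim$reference$values)
  start <- sim$informative
  pr <- frog_params(n_iterations = 60, n_selected = 5, theta = 1e-9,
                    eta = 0, n_folds = 4, seed = 4, initial_subset = start)
  a <- random_frog_select(X, y, pr)
  # proposal size never moves, so the subset is retained every iteration
  expect_equal(a$diagnostics$probability[start], rep(1, length(start)))
  expect_identical(a$selected_indices, sort(start))
})

test_that("reduction_percent reports two-decimal wavelength economy", {
  expect_identical(reduction_percent(26, 1557), 98.33)
  expect_identical(reduction_percent(40, 1557), 97.43)
  expect_identical(reduction_percent(100, 100), 0)
  expect_error(reduction_percent(101, 100), "exceeds")
  expect_error(reduction_percent(0, 100), "positive")
})
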