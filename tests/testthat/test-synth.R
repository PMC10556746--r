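test_that("default configs carry the reference concentration ranges and grid", {
  expect_equal(default_milk_powder_config("GOS", seed = 1)$conc_range, c(5, 29))
  expect_equal(default_milk_powder_config("FOS", seed = 1)$conc_range, c(4.4, 26.6))
  expect_equal(default_milk_powder_config("Ca", seed = 1)$conc_range, c(3.1, 7.12))
  expect_equal(default_milk_powder_config("Vc", seed = 1)$conc_range, c(0.54, 1.82))
  for (an in c("GOS", "FOS", "Ca", "Vc")) {
    cfg <- default_milk_powder_config(an, seed = 1)
    expect_identical(cfg$n_points, 1557L)
    expect_equal(c(cfg$wn_min, cfg$wn_max), c(4000, 12500))
  }
  expect_error(default_milk_powder_config("vitamin Q"), "GOS")
})

test_that("pure_component_spectrum follows the Gaussian band model", {
  grid <- seq(4000, 9000, by = 100)
  b <- band_spec(6000, 150, 0.4)
  v <- pure_component_spectrum(list(b), grid)
  expect_equal(v[grid == 6000], 0.4)          # amplitude at the mode
  expect_equal(pure_component_spectrum(list(), grid), numeric(length(grid)))
  expect_equal(pure_component_spectrum(list(b, b), grid), 2 * v)  # linearity
  expect_true(all(v >= 0))
})

test_that("with artifacts disabled the spectra obey Beer-Lambert exactly", {
  cfg <- clean_config(n_samples = 6, seed = 2)
  sim <- simulate_dataset(cfg)
  grid <- sim$spectra$wavenumbers
  pure <- pure_component_spectrum(cfg$analyte_bands, grid)
  bg <- pure_component_spectrum(cfg$matrix_bands, grid)
  conc <- unname(sim$reference$values)
  for (i in seq_len(6)) {
    expect_equal(unname(sim$spectra$absorbance[i, ]) - bg, conc[i] * pure,
                 tolerance = 1e-12)
  }
  # difference of two samples isolates the analyte signal
  d <- unname(sim$spectra$absorbance[1, ] - sim$spectra$absorbance[2, ])
  expect_equal(d, (conc[1] - conc[2]) * pure, tolerance = 1e-12)
})

test_that("simulation is deterministic under its seed", {
  cfg <- default_milk_powder_config("FOS", n_points = 80, n_samples = 10,
                                    seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$reference$values, b$reference$values)
  c_ <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(a$spectra$absorbance, c_$spectra$absorbance))
})

test_that("concentrations stay in range; ground truth is non-empty and in bounds", {
  for (an in c("GOS", "FOS", "Ca", "Vc")) {
    cfg <- default_milk_powder_config(an, n_points = 200, n_samples = 25,
                                      seed = 8)
    sim <- simulate_dataset(cfg)
    expect_true(all(sim$reference$values >= cfg$conc_range[1]))
    expect_true(all(sim$reference$values <= cfg$conc_range[2]))
    expect_gt(length(sim$informative), 0L)
    expect_true(all(sim$informative >= 1L & sim$informative <= cfg$n_points))
  }
})

test_that("absorbance at the analyte band center tracks concentration", {
  cfg <- default_milk_powder_config("GOS", n_samples = 60,
                                    scatter_slope = c(1, 1),
                                    scatter_offset = c(0, 0), tilt = c(0, 0),
                                    matrix_jitter = 0, noise_sd = 1e-4,
                                    seed = 11)
  sim <- simulate_dataset(cfg)
  center <- cfg$analyte_bands[[1]]$center
  j <- which.min(abs(sim$spectra$wavenumbers - center))
  r <- cor(unname(sim$reference$values), sim$spectra$absorbance[, j])
  expect_gt(r, 0.9)
})

test_that("SNV removes multiplicative and additive scatter exactly", {
  cfg <- default_milk_powder_config("Ca", n_points = 120, n_samples = 8,
                                    tilt = c(0, 0), matrix_jitter = 0,
                                    noise_sd = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  grid <- sim$spectra$wavenumbers
  pure <- pure_component_spectrum(cfg$analyte_bands, grid)
  bg <- pure_component_spectrum(cfg$matrix_bands, grid)
  clean <- outer(unname(sim$reference$values), pure) +
    rep(1, 8) %o% bg
  expect_equal(unname(snv(sim$spectra$absorbance)), snv(clean),
               tolerance = 1e-9)
})

test_that("the selector fixture plants exactly 5 informative wavelengths", {
  sim <- simulate_dataset(informative_fixture_config())
  expect_length(sim$informative, 5L)
})

test_that("degenerate simulation requests error cleanly", {
  cfg <- clean_config(n_samples = 5, seed = 1)
  cfg$n_samples <- 1L
  expect_error(simulate_dataset(cfg), "n_samples")
  expect_error(simulation_config(analyte_bands = list(band_spec(5000, 10, 1)),
                                 conc_range = c(2, 1)), "low < high")
  expect_error(simulation_config(analyte_bands = list(band_spec(500, 10, 1))),
               "outside")
})
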