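# Fixtures built in code; nothing is read from disk.

# Random spectra on an arbitrary ascending grid.
random_spectra <- function(n = 5, p = 10, seed = 7) {
  set.seed(seed)
  spectra_set(sort(runif(p, 4000, 12000)),
              matrix(runif(n * p), n, p),
              sprintf("S%02d", seq_len(n)))
}

# Benchmark fixture for the selectors: 100-point grid with one narrow
# analyte band whose pure spectrum exceeds 10% of its maximum at exactly
# 5 grid points (verified in test-synth), broad background bands, scatter
# and background jitter disabled.
informative_fixture_config <- function(n_samples = 60, noise_sd = 1e-3,
                                       seed = 21) {
  simulation_config(
    n_points = 100, wn_min = 4000, wn_max = 12500, n_samples = n_samples,
    analyte = "GOS", conc_range = c(5, 29),
    analyte_bands = list(band_spec(8000, 100, 5e-4)),
    matrix_bands = list(band_spec(5200, 400, 0.5),
                        band_spec(6900, 500, 0.3)),
    scatter_slope = c(1, 1), scatter_offset = c(0, 0), tilt = c(0, 0),
    matrix_jitter = 0, noise_sd = noise_sd, seed = seed)
}

# Small clean config: linear response, no artifacts; for exact oracles.
clean_config <- function(n_samples = 30, n_points = 150, noise_sd = 0,
                         analyte = "GOS", seed = 2) {
  default_milk_powder_config(
    analyte, n_points = n_points, n_samples = n_samples,
    scatter_slope = c(1, 1), scatter_offset = c(0, 0), tilt = c(0, 0),
    matrix_jitter = 0, noise_sd = noise_sd, seed = seed)
}
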