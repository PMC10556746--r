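# Synthetic milk-powder NIR generator.
#
# A spectrum is modelled as a matrix background plus a Beer-Lambert analyte
# term, both sums of Gaussian absorption bands, degraded by per-sample
# multiplicative scatter, an additive offset, a linear baseline tilt and
# i.i.d. Gaussian noise:
#
#   x_i = m_i * (background + c_i * pure) + a_i + t_i * s(wn) + eps_i
#
# where s(wn) ramps linearly from 0 to 1 across the grid. The indices where
# the analyte's pure-component spectrum exceeds 10% of its maximum are
# returned as the "informative" ground truth for selector benchmarks.

#' Specify a Gaussian absorption band
#'
#' @param center band center in cm^-1.
#' @param width Gaussian sigma in cm^-1, > 0.
#' @param amplitude peak absorbance; for analyte bands this is absorbance
#'   per mg/kg of analyte, > 0.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, width, amplitude) {
  if (!is.numeric(center) || !is.finite(center)) stop_nircal("bad band center")
  if (!is.numeric(width) || width <= 0) stop_nircal("band width must be > 0")
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop_nircal("band amplitude must be > 0")
  }
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

#' Configure a synthetic NIR simulation
#'
#' See [default_milk_powder_config()] for ready-made per-analyte defaults;
#' this constructor validates an arbitrary configuration.
#'
#' @param n_points grid size (default 1557 points).
#' @param wn_min,wn_max grid span in cm^-1 (default 4000-12500, the
#'   wavenumber equivalent of 800-2500 nm).
#' @param n_samples number of samples to draw.
#' @param analyte analyte label.
#' @param conc_range length-2 numeric `(low, high)` concentration range in
#'   mg/kg, low < high; concentrations are drawn uniformly from it.
#' @param analyte_bands list of [band_spec()]: the analyte's pure-component
#'   bands (amplitude per mg/kg).
#' @param matrix_bands list of [band_spec()]: the milk-powder background
#'   common to all samples (fixed amplitudes).
#' @param scatter_slope length-2 range of the per-sample multiplicative
#'   scatter factor (default 0.8-1.2).
#' @param scatter_offset length-2 range of the per-sample additive offset
#'   in AU (default -0.05 to 0.05).
#' @param tilt length-2 range of the linear baseline tilt across the grid,
#'   in AU (default -0.05 to 0.05).
#' @param matrix_jitter lognormal sd of the per-sample, per-band
#'   variation of the matrix-band amplitudes (default 0.15): each sample's
#'   background band k is scaled by `exp(matrix_jitter * z_ik)`,
#'   `z ~ N(0,1)`. Emulates compositional variation of the powder matrix
#'   across products; 0 gives a background common to all samples.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise per
#'   point, in AU (default 1e-3).
#' @param seed default seed used by [simulate_dataset()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_points = 1557, wn_min = 4000, wn_max = 12500,
                              n_samples = 120, analyte = "unknown",
                              conc_range = c(0, 1),
                              analyte_bands, matrix_bands = list(),
                              scatter_slope = c(0.8, 1.2),
                              scatter_offset = c(-0.05, 0.05),
                              tilt = c(-0.05, 0.05), matrix_jitter = 0.15,
                              noise_sd = 1e-3, seed = NULL) {
  if (!is_count(n_points) || n_points < 2) stop_nircal("n_points must be >= 2")
  if (wn_min >= wn_max) stop_nircal("wn_min must be < wn_max")
  if (length(conc_range) != 2L || conc_range[1L] >= conc_range[2L]) {
    stop_nircal("conc_range must be (low, high) with low < high")
  }
  if (any(conc_range < 0)) stop_nircal("concentrations must be non-negative")
  if (noise_sd < 0) stop_nircal("noise_sd must be >= 0")
  if (matrix_jitter < 0) stop_nircal("matrix_jitter must be >= 0")
  if (missing(analyte_bands) || length(analyte_bands) == 0L) {
    stop_nircal("at least one analyte band is required")
  }
  for (b in c(analyte_bands, matrix_bands)) {
    stopifnot(inherits(b, "band_spec"))
    if (b$center < wn_min || b$center > wn_max) {
      stop_nircal("band center ", b$center, " outside grid [", wn_min, ", ",
                  wn_max, "]")
    }
  }
  rng2 <- function(r) {
    if (length(r) != 2L || r[1L] > r[2L]) stop_nircal("ranges must be (lo, hi)")
    as.numeric(r)
  }
  structure(list(n_points = as.integer(n_points), wn_min = wn_min,
                 wn_max = wn_max, n_samples = as.integer(n_samples),
                 analyte = analyte, conc_range = as.numeric(conc_range),
                 analyte_bands = analyte_bands, matrix_bands = matrix_bands,
                 scatter_slope = rng2(scatter_slope),
                 scatter_offset = rng2(scatter_offset), tilt = rng2(tilt),
                 matrix_jitter = matrix_jitter,
                 noise_sd = noise_sd, seed = seed),
            class = "simulation_config")
}

# Invented analyte band positions (config data, not chemistry claims):
# 2-3 bands per analyte in the overtone/combination regions, distinct per
# analyte and offset from the five background peaks.
.analyte_band_table <- list(
  GOS = list(c(4400, 60, 4.5e-4), c(6950, 80, 3.5e-4), c(8400, 70, 2.5e-4)),
  FOS = list(c(4300, 60, 5.5e-4), c(7100, 80, 4.5e-4), c(8600, 70, 3.0e-4)),
  Ca  = list(c(5600, 70, 2.0e-3), c(9000, 90, 1.5e-3)),
  Vc  = list(c(4500, 60, 7.0e-3), c(6100, 70, 5.0e-3), c(8800, 80, 3.5e-3))
)

# Reference ranges for the four analytes (mg/kg), as reported by the
# wet-chemistry methods.
.conc_range_table <- list(GOS = c(5, 29), FOS = c(4.4, 26.6),
                          Ca = c(3.1, 7.12), Vc = c(0.54, 1.82))

#' Default simulation configuration for a milk-powder analyte
#'
#' Grid of 1557 points spanning 4000-12500 cm^-1; background bands at the
#' five characteristic milk-powder peaks (8246, 6700, 5770, 5180 and
#' 4748 cm^-1); 2-3 invented analyte-specific bands; the analyte's
#' reference concentration range (GOS 5-29, FOS 4.4-26.6, Ca 3.1-7.12,
#' Vc 0.54-1.82 mg/kg).
#'
#' @param analyte one of `"GOS"`, `"FOS"`, `"Ca"`, `"Vc"`.
#' @param ... overrides passed on to [simulation_config()] (e.g.
#'   `n_samples`, `noise_sd`, `seed`).
#' @return A `simulation_config`.
#' @export
#' @examples
#' cfg <- default_milk_powder_config("GOS", seed = 1)
#' cfg$conc_range
default_milk_powder_config <- function(analyte, ...) {
  if (!analyte %in% names(.conc_range_table)) {
    stop_nircal("unknown analyte '", analyte, "'; valid labels: ",
                paste(names(.conc_range_table), collapse = ", "))
  }
  # five principal milk-powder peaks plus a set of secondary constituent
  # bands (fat/protein/lactose/mineral overtones and combinations) with
  # amplitudes decaying toward high wavenumber, as in real NIR absorbance;
  # per-sample jitter of these amplitudes emulates compositional variation
  matrix_bands <- list(
    band_spec(4748, 120, 0.55), band_spec(5180,  90, 0.70),
    band_spec(5770, 110, 0.45), band_spec(6700, 150, 0.30),
    band_spec(8246, 180, 0.18),
    band_spec(4150, 180, 0.42), band_spec(4900, 120, 0.33),
    band_spec(5350, 240, 0.26),
    band_spec(5950, 200, 0.035), band_spec(6420, 110, 0.030),
    band_spec(7150, 180, 0.025), band_spec(7420, 140, 0.030),
    band_spec(7700, 280, 0.025), band_spec(8550, 320, 0.022),
    band_spec(8900, 180, 0.018), band_spec(9300, 260, 0.015),
    band_spec(10150, 300, 0.012), band_spec(11000, 280, 0.010))
  analyte_bands <- lapply(.analyte_band_table[[analyte]],
                          function(b) band_spec(b[1L], b[2L], b[3L]))
  args <- list(analyte = analyte, conc_range = .conc_range_table[[analyte]],
               analyte_bands = analyte_bands, matrix_bands = matrix_bands)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Pure-component spectrum of a set of Gaussian bands
#'
#' Sums `amplitude * exp(-(wn - center)^2 / (2 width^2))` over the bands.
#' An empty band list yields the zero vector.
#'
#' @param bands list of [band_spec()] (possibly empty).
#' @param grid numeric wavenumber vector.
#' @return Non-negative absorbance vector, `length(grid)`.
#' @export
pure_component_spectrum <- function(bands, grid) {
  out <- numeric(length(grid))
  for (b in bands) {
    out <- out + b$amplitude * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  out
}

#' Simulate a synthetic NIR dataset
#'
#' Draws per-sample concentrations uniformly from the configured range and
#' builds each spectrum as scatter-degraded Beer-Lambert mixture of the
#' matrix background and the analyte pure-component spectrum (see the
#' package vignette for the generative model). Deterministic under
#' `seed`; draw order is concentrations, scatter slopes, offsets, tilts,
#' then the noise matrix.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return A list of class `nir_simulation` with components `spectra`
#'   (a [spectra_set()]), `reference` (a [concentration_table()]) and
#'   `informative` (integer indices where the analyte pure spectrum
#'   exceeds 10% of its maximum -- the selector ground truth).
#' @export
#' @examples
#' sim <- simulate_dataset(default_milk_powder_config("Vc", n_samples = 8,
#'                                                    n_points = 50, seed = 2))
#' sim$spectra
#' range(sim$reference$values)
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_samples
  if (n < 2L) stop_nircal("n_samples must be >= 2")
  if (is.null(seed)) stop_nircal("a seed is required (cfg$seed or the seed argument)")
  grid <- seq(cfg$wn_min, cfg$wn_max, length.out = cfg$n_points)
  pure <- pure_component_spectrum(cfg$analyte_bands, grid)
  ramp <- (grid - cfg$wn_min) / (cfg$wn_max - cfg$wn_min)
  nb <- length(cfg$matrix_bands)
  # one grid profile per matrix band so per-sample amplitudes can vary
  band_profiles <- vapply(cfg$matrix_bands, function(b) {
    pure_component_spectrum(list(b), grid)
  }, numeric(cfg$n_points))
  X <- with_seed(seed, {
    conc <- stats::runif(n, cfg$conc_range[1L], cfg$conc_range[2L])
    m <- stats::runif(n, cfg$scatter_slope[1L], cfg$scatter_slope[2L])
    a <- stats::runif(n, cfg$scatter_offset[1L], cfg$scatter_offset[2L])
    tl <- stats::runif(n, cfg$tilt[1L], cfg$tilt[2L])
    jit <- if (nb > 0L) {
      matrix(exp(cfg$matrix_jitter * stats::rnorm(n * nb)), nrow = n)
    } else {
      matrix(0, n, 0L)
    }
    eps <- matrix(stats::rnorm(n * cfg$n_points, sd = cfg$noise_sd),
                  nrow = n)
    bg_rows <- if (nb > 0L) jit %*% t(band_profiles) else matrix(0, n, cfg$n_points)
    out <- sweep(outer(conc, pure) + bg_rows, 1, m, "*") + a +
      tl %o% ramp + eps
    attr(out, "conc") <- conc
    out
  })
  conc <- attr(X, "conc"); attr(X, "conc") <- NULL
  ids <- sprintf("S%03d", seq_len(n))
  list2 <- list(
    spectra = spectra_set(grid, X, ids),
    reference = concentration_table(ids, conc, analyte = cfg$analyte),
    informative = which(pure > 0.1 * max(pure)))
  structure(list2, class = "nir_simulation")
}

#' @export
print.nir_simulation <- function(x, ...) {
  print(x$spectra)
  print(x$reference)
  cat("Informative wavelengths (ground truth):", length(x$informative), "\n")
  invisible(x)
}
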