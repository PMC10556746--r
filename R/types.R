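# Domain containers: spectra_set, concentration_table, split_assignment.
# All are plain lists with a class attribute and a strict validator, in the
# style of base-R modelling objects.

#' Construct a spectra set
#'
#' The X block of every calibration: an absorbance matrix on a shared,
#' strictly increasing wavenumber grid (cm^-1), one row per sample.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, all finite.
#' @param absorbance numeric matrix, `n_samples x length(wavenumbers)`,
#'   all finite. Unitless absorbance.
#' @param sample_ids character vector of unique sample identifiers,
#'   one per row of `absorbance`.
#' @return An object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance` (row/col-named) and `sample_ids`.
#' @export
#' @examples
#' s <- spectra_set(c(4000, 4004), matrix(1:4 / 10, 2), c("A", "B"))
#' s
spectra_set <- function(wavenumbers, absorbance, sample_ids) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 1L || any(!is.finite(wavenumbers))) {
    stop_nircal("wavenumbers must be finite and non-empty")
  }
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0)) {
    stop_nircal("wavenumbers must be strictly increasing")
  }
  if (!is.matrix(absorbance)) absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (nrow(absorbance) < 1L) stop_nircal("need at least one sample")
  if (ncol(absorbance) != length(wavenumbers)) {
    stop_nircal("absorbance has ", ncol(absorbance), " columns but there are ",
                length(wavenumbers), " wavenumbers")
  }
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop_nircal("non-finite absorbance at row ", bad[1L], ", column ", bad[2L])
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop_nircal("sample_ids length must equal the number of spectra")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop_nircal("duplicate sample id '", dup, "'")
  }
  dimnames(absorbance) <- list(sample_ids, format(wavenumbers, trim = TRUE))
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("NIR spectra set: ", nrow(x$absorbance), " samples x ",
      length(x$wavenumbers), " wavelengths (",
      format(min(x$wavenumbers)), "-", format(max(x$wavenumbers)),
      " cm^-1)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Construct a concentration table
#'
#' The y block: one reference concentration per sample for a single analyte,
#' from the wet-chemistry reference method.
#'
#' @param sample_ids unique character ids, matching a [spectra_set()] when
#'   the two are paired.
#' @param values non-negative finite concentrations.
#' @param analyte analyte label, e.g. `"GOS"`, `"FOS"`, `"Ca"`, `"Vc"`.
#' @param units unit string; defaults to mg/kg as used throughout.
#' @return An object of class `concentration_table`.
#' @export
concentration_table <- function(sample_ids, values, analyte = "unknown",
                                units = "mg/kg") {
  sample_ids <- as.character(sample_ids)
  values <- as.numeric(values)
  if (length(sample_ids) != length(values)) {
    stop_nircal("sample_ids and values must have equal length")
  }
  if (anyDuplicated(sample_ids)) {
    stop_nircal("duplicate sample id '",
                sample_ids[duplicated(sample_ids)][1L], "'")
  }
  if (any(!is.finite(values))) stop_nircal("concentrations must be finite")
  if (any(values < 0)) {
    i <- which(values < 0)[1L]
    stop_nircal("negative concentration for sample '", sample_ids[i], "'")
  }
  structure(list(sample_ids = sample_ids, values = stats::setNames(values, sample_ids),
                 analyte = as.character(analyte)[1L],
                 units = as.character(units)[1L]),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("Concentrations of ", x$analyte, " (", x$units, "): ",
      length(x$values), " samples, range ",
      format(min(x$values)), "-", format(max(x$values)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.concentration_table <- function(x, ...) {
  data.frame(id = x$sample_ids, value = unname(x$values),
             analyte = x$analyte, units = x$units,
             stringsAsFactors = FALSE)
}

# Check a spectra_set / concentration_table pair and return y reordered to
# the spectra's sample order.
pair_xy <- function(s, y) {
  stopifnot(inherits(s, "spectra_set"), inherits(y, "concentration_table"))
  if (!setequal(s$sample_ids, y$sample_ids) ||
      length(s$sample_ids) != length(y$sample_ids)) {
    stop_nircal("sample ids of spectra and concentrations do not match 1:1")
  }
  unname(y$values[s$sample_ids])
}

#' Split samples into calibration and prediction sets
#'
#' Random partition of the samples under an explicit seed. A uniformly
#' random permutation is drawn and the first `round(ratio * n)` samples
#' (ties rounded up) form the calibration set; the rest form the
#' prediction set. The conventional split for this workflow is 7:3.
#'
#' @param s a [spectra_set()].
#' @param y a paired [concentration_table()].
#' @param ratio calibration fraction in (0, 1); default 0.7.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return An object of class `split_assignment` with sorted integer
#'   `calibration` and `prediction` index vectors, plus `ratio` and `seed`.
#' @export
#' @examples
#' sim <- simulate_dataset(default_milk_powder_config("Vc", n_samples = 10,
#'                                                    n_points = 20, seed = 1))
#' split_calibration_prediction(sim$spectra, sim$reference, 0.7, seed = 4)
split_calibration_prediction <- function(s, y, ratio = 0.7, seed) {
  pair_xy(s, y)
  n <- nrow(s$absorbance)
  if (n < 4L) stop_nircal("need at least 4 samples to form both sets")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop_nircal("ratio must lie strictly between 0 and 1")
  }
  perm <- with_seed(seed, sample.int(n))
  n_cal <- as.integer(floor(ratio * n + 0.5))  # ties round up
  n_cal <- max(1L, min(n - 1L, n_cal))
  structure(list(calibration = sort(perm[seq_len(n_cal)]),
                 prediction = sort(perm[-seq_len(n_cal)]),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Calibration/prediction split: ", length(x$calibration), "/",
      length(x$prediction), " samples (ratio ", format(x$ratio),
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
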