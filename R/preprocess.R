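# Spectral pretreatments: SNV, MSC, per-row min-max normalization and
# Savitzky-Golay smoothing. SNV, normalization and SG are stateless and
# row-local; MSC carries fit state (the reference spectrum), handled by
# fit_preprocessor()/apply_preprocessor() so that prediction-set rows are
# corrected against the calibration mean only.

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and unit sample
#' standard deviation (n-1 denominator). Removes per-sample additive and
#' multiplicative scatter.
#'
#' @param X numeric matrix, samples in rows.
#' @return Matrix of the same shape; each row has mean 0, sd 1.
#' @export
#' @examples
#' snv(matrix(c(1, 2, 3), 1))
snv <- function(X) {
  X <- as_matrix_x(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    stop_nircal("constant spectrum: SNV undefined for ", row_label(X, bad[1L]))
  }
  out <- (X - mu) / sdv
  dimnames(out) <- dimnames(X)
  out
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x = a + b * ref`, and returns `(x - a) / b`. With
#' `reference = "mean"` the column mean of `X` itself is used; in a
#' calibration pipeline use [fit_preprocessor()] so the calibration-set
#' mean is frozen and reused for prediction rows.
#'
#' @param X numeric matrix, samples in rows.
#' @param reference `"mean"` or a numeric vector of length `ncol(X)`.
#' @return Corrected matrix of the same shape.
#' @export
msc <- function(X, reference = "mean") {
  X <- as_matrix_x(X)
  if (ncol(X) < 2L) stop_nircal("MSC needs at least 2 wavelengths")
  ref <- if (identical(reference, "mean")) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X)) stop_nircal("reference length must equal ncol(X)")
  if (stats::sd(ref) <= 0) stop_nircal("MSC reference spectrum is constant")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  b <- as.numeric((X - rowMeans(X)) %*% rc) / denom
  a <- rowMeans(X) - b * mean(ref)
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    stop_nircal("MSC slope ~ 0 for ", row_label(X, bad[1L]))
  }
  out <- (X - a) / b
  dimnames(out) <- dimnames(X)
  out
}

#' Per-row min-max normalization
#'
#' Rescales each spectrum to span `[0, 1]`:
#' `(x - min(x)) / (max(x) - min(x))`.
#'
#' @param X numeric matrix, samples in rows.
#' @return Matrix of the same shape with per-row min 0 and max 1.
#' @export
normalize_minmax <- function(X) {
  X <- as_matrix_x(X)
  lo <- apply(X, 1L, min)
  hi <- apply(X, 1L, max)
  bad <- which(hi - lo <= 0)
  if (length(bad)) {
    stop_nircal("constant spectrum: normalization undefined for ",
                row_label(X, bad[1L]))
  }
  out <- (X - lo) / (hi - lo)
  dimnames(out) <- dimnames(X)
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (derivative order 0) of each
#' spectrum, via [signal::sgolayfilt()]. Edges are handled by the filter's
#' transient least-squares fits on the available window -- no padding.
#'
#' @param X numeric matrix, samples in rows.
#' @param window odd window length, `3 <= window < ncol(X)`.
#' @param order polynomial order, `order < window`.
#' @return Smoothed matrix of the same shape.
#' @export
savitzky_golay <- function(X, window = 11L, order = 2L) {
  X <- as_matrix_x(X)
  if (!is_count(window) || window %% 2L == 0L) {
    stop_nircal("window must be an odd integer")
  }
  if (window < 3L || window > ncol(X)) {
    stop_nircal("window must lie in [3, ncol(X)]")
  }
  if (!is_count(order) || order < 0 || order >= window) {
    stop_nircal("order must satisfy 0 <= order < window")
  }
  out <- t(apply(X, 1L, signal::sgolayfilt, p = order, n = window, m = 0))
  dimnames(out) <- dimnames(X)
  out
}

#' Fit a preprocessor on the calibration block
#'
#' Captures any fit state a pretreatment needs (for MSC, the calibration
#' mean spectrum) so it can be applied identically to calibration and
#' prediction rows without information leakage.
#'
#' @param method one of `"none"`, `"snv"`, `"msc"`, `"norm"`, `"sg"`.
#' @param X_cal calibration absorbance matrix.
#' @param sg_window,sg_order Savitzky-Golay parameters (used when
#'   `method = "sg"`).
#' @param msc_reference `"mean"` (calibration mean) or a numeric vector.
#' @return An object of class `nir_preprocessor` for
#'   [apply_preprocessor()].
#' @export
fit_preprocessor <- function(method = c("none", "snv", "msc", "norm", "sg"),
                             X_cal, sg_window = 11L, sg_order = 2L,
                             msc_reference = "mean") {
  method <- match.arg(method)
  X_cal <- as_matrix_x(X_cal)
  state <- switch(method,
    msc = list(reference = if (identical(msc_reference, "mean"))
                 colMeans(X_cal) else as.numeric(msc_reference)),
    sg = list(window = as.integer(sg_window), order = as.integer(sg_order)),
    list())
  structure(list(method = method, state = state), class = "nir_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param pp an object from [fit_preprocessor()].
#' @param X absorbance matrix (calibration or prediction rows).
#' @return Pretreated matrix of the same shape.
#' @export
apply_preprocessor <- function(pp, X) {
  stopifnot(inherits(pp, "nir_preprocessor"))
  X <- as_matrix_x(X)
  switch(pp$method,
         none = X,
         snv = snv(X),
         msc = msc(X, reference = pp$state$reference),
         norm = normalize_minmax(X),
         sg = savitzky_golay(X, pp$state$window, pp$state$order))
}
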