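# Partial least squares regression, univariate y, NIPALS algorithm.
# Coefficients are produced for every component count 1..A in one pass
# (cumulative B from the weight/loading triangular system), which is what
# makes the cross-validated latent-variable search and the selector
# internals cheap.

# Core fit on raw X, y. Returns per-component coefficient matrix on the
# ORIGINAL scale of X: coef[, a] are the slopes using `a` latent variables,
# intercept[a] the matching intercept. `scale = TRUE` autoscales X columns
# before fitting (used for selector weights so coefficient magnitudes are
# comparable across wavelengths).
pls_core <- function(X, y, ncomp, scale = FALSE) {
  X <- as_matrix_x(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop_nircal("PLSR needs at least one predictor column")
  if (n != length(y)) stop_nircal("X rows and y length differ")
  ncomp <- min(ncomp, p, n - 1L)
  if (ncomp < 1L) stop_nircal("cannot fit PLSR: need >= 2 samples")
  xm <- colMeans(X)
  xs <- rep(1, p)
  Xc <- X - rep(xm, each = n)
  if (scale) {
    xs <- apply(X, 2L, stats::sd)
    xs[xs < 1e-12] <- 1
    Xc <- Xc / rep(xs, each = n)
  }
  ym <- mean(y)
  yd <- y - ym
  Xd <- Xc
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # y residual orthogonal to X: stop early
    w <- w / wn
    tt <- Xd %*% w
    tsq <- sum(tt^2)
    if (tsq < 1e-24) break
    pl <- crossprod(Xd, tt) / tsq
    q <- sum(yd * tt) / tsq
    Xd <- Xd - tt %*% t(pl)
    yd <- yd - q * as.numeric(tt)
    W[, a] <- w; P[, a] <- pl; Q[a] <- q
    a_used <- a
  }
  if (a_used == 0L) {
    # y uncorrelated with X (e.g. constant y): intercept-only model
    return(list(coef = matrix(0, p, 1L), intercept = ym, ncomp = 1L,
                x_means = xm, x_scales = xs, y_mean = ym))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[seq_len(a_used)]
  # R = W (P'W)^-1; P'W is upper triangular, so R[, 1:a] gives the
  # a-component solution for every a at once.
  R <- W %*% backsolve(crossprod(P, W), diag(a_used))
  B <- matrix(0, p, a_used)
  acc <- numeric(p)
  for (a in seq_len(a_used)) {
    acc <- acc + R[, a] * Q[a]
    B[, a] <- acc
  }
  B <- B / xs
  list(coef = B, intercept = ym - as.numeric(crossprod(xm, B)),
       ncomp = a_used, x_means = xm, x_scales = xs, y_mean = ym)
}

# Seeded k-fold assignment.
cv_folds <- function(n, k, seed = NULL) {
  if (k < 2L) stop_nircal("need at least 2 folds")
  if (n < k) stop_nircal("fewer samples (", n, ") than folds (", k, ")")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated RMSE of PLSR over latent-variable counts
#'
#' k-fold cross-validation (seeded fold shuffle) of a PLSR fit for each
#' latent-variable count `1..max_lv` (capped by the rank bound of the
#' smallest training fold), returning the minimum RMSECV and the count
#' achieving it (ties go to the smaller count).
#'
#' @param X predictor matrix (samples x wavelengths).
#' @param y response vector.
#' @param n_folds number of CV folds (>= 2).
#' @param max_lv maximum latent variables to consider.
#' @param seed integer seed for the fold shuffle; `NULL` uses the ambient
#'   RNG stream.
#' @return List with `best_rmsecv`, `best_lv` and the full `rmsecv_by_lv`
#'   vector.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20)
#' y <- 2 * X[, 1]
#' rmsecv(X, y, n_folds = 5, max_lv = 3, seed = 1)
rmsecv <- function(X, y, n_folds = 10L, max_lv = 10L, seed = NULL) {
  X <- as_matrix_x(X)
  n <- nrow(X)
  folds <- cv_folds(n, n_folds, seed)
  A <- min(max_lv, ncol(X), (n - max(tabulate(folds, n_folds))) - 1L)
  if (A < 1L) stop_nircal("too few samples per training fold for PLSR")
  sse <- numeric(A)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit <- pls_core(X[tr, , drop = FALSE], y[tr], A)
    a_f <- fit$ncomp
    Xte <- X[!tr, , drop = FALSE]
    pred <- Xte %*% fit$coef + rep(fit$intercept, each = nrow(Xte))
    if (a_f < A) {  # early-stopped fit: extend with its last column
      pred <- cbind(pred, matrix(pred[, a_f], nrow(pred), A - a_f))
    }
    sse <- sse + colSums((pred - y[!tr])^2)
  }
  rmse_lv <- sqrt(sse / n)
  best <- which.min(rmse_lv)
  list(best_rmsecv = rmse_lv[best], best_lv = as.integer(best),
       rmsecv_by_lv = rmse_lv)
}

#' Fit a cross-validated PLSR calibration model
#'
#' Chooses the number of latent variables by k-fold RMSECV (ties to the
#' smaller count), then refits on all rows with that count.
#'
#' @inheritParams rmsecv
#' @param subset optional integer wavelength indices (into the full grid)
#'   that `X`'s columns correspond to; stored so [predict.plsr_model()]
#'   can slice full-grid input.
#' @param n_full full grid size for `subset` bookkeeping.
#' @return An object of class `plsr_model`.
#' @export
fit_plsr <- function(X, y, max_lv = 10L, n_folds = 10L, seed = NULL,
                     subset = NULL, n_full = NULL) {
  X <- as_matrix_x(X)
  if (ncol(X) < 1L) stop_nircal("no predictor columns")
  cv <- rmsecv(X, y, n_folds = n_folds, max_lv = max_lv, seed = seed)
  fit <- pls_core(X, y, cv$best_lv)
  lv <- min(cv$best_lv, fit$ncomp)
  structure(list(coefficients = fit$coef[, lv],
                 intercept = fit$intercept[lv],
                 n_latent_variables = lv,
                 cv = cv,
                 x_means = fit$x_means,
                 subset = if (is.null(subset)) seq_len(ncol(X)) else as.integer(subset),
                 n_full = if (is.null(n_full)) ncol(X) else as.integer(n_full),
                 fitted_values = as.numeric(X %*% fit$coef[, lv] + fit$intercept[lv])),
            class = "plsr_model")
}

#' Predict from a PLSR calibration model
#'
#' Accepts either the training wavelength subset or the full grid (the
#' stored subset is applied internally, so pipelines cannot misalign
#' columns).
#'
#' @param object a `plsr_model`.
#' @param newdata numeric matrix (or [spectra_set()]).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- as_matrix_x(newdata)
  X <- slice_to_subset(X, object)
  as.numeric(X %*% object$coefficients + object$intercept)
}

slice_to_subset <- function(X, m) {
  ns <- length(m$subset)
  if (ncol(X) == ns) return(X)
  if (ncol(X) == m$n_full) return(X[, m$subset, drop = FALSE])
  stop_nircal("newdata has ", ncol(X), " columns; expected ", ns,
              " (training subset) or ", m$n_full, " (full grid)")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("PLSR calibration model: ", x$n_latent_variables, " latent variables, ",
      length(x$coefficients), " wavelengths (RMSECV ",
      format(x$cv$best_rmsecv, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.plsr_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$coefficients,
                    paste0("wl", object$subset)))
}
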