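# RBF-kernel epsilon-SVR with an exhaustive (c, g) grid search.
# c and g are log2 exponents (C = 2^c, gamma = 2^g), the dominant
# convention for SVR grids; `grid_linear = TRUE` reads them as linear
# values instead. Fitting is delegated to e1071::svm; the prediction path
# is the explicit kernel expansion over the stored support coefficients,
# so a model serialized to JSON round-trips exactly.

#' Fit an RBF-kernel SVR calibration model by grid search
#'
#' Exhaustive search over the `(c, g)` grid (default `[-10, 10]` in steps
#' of 0.5, i.e. 41 x 41 = 1681 cells), each cell scored by k-fold CV RMSE
#' on the calibration block; the argmin (ties: smaller C, then smaller
#' gamma) is refit on all calibration rows. Predictor columns are
#' autoscaled with calibration statistics before fitting, as kernel
#' methods require.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response vector (must not be constant).
#' @param c_grid,g_grid exponent grids; `C = 2^c`, `gamma = 2^g` unless
#'   `grid_linear`.
#' @param epsilon epsilon-tube half-width on the standardized response
#'   axis, i.e. in units of sd(y) (default 0.01).
#' @param n_folds CV folds for the grid search.
#' @param seed integer seed for the fold shuffle.
#' @param grid_linear interpret `c_grid`/`g_grid` as linear `C`/`gamma`.
#' @param subset,n_full wavelength-subset bookkeeping as in [fit_plsr()].
#' @return An object of class `svr_model`; `cv_table` is a data frame with
#'   one row per grid cell (`c`, `g`, `cv_rmse`).
#' @export
fit_svr_grid <- function(X, y, c_grid = seq(-10, 10, by = 0.5),
                         g_grid = seq(-10, 10, by = 0.5), epsilon = 0.01,
                         n_folds = 5L, seed = NULL, grid_linear = FALSE,
                         subset = NULL, n_full = NULL) {
  X <- as_matrix_x(X)
  n <- nrow(X)
  if (length(y) != n) stop_nircal("X rows and y length differ")
  if (stats::sd(y) <= 0) stop_nircal("constant response: SVR undefined")
  if (length(c_grid) < 1L || length(g_grid) < 1L) stop_nircal("empty grid")
  xm <- colMeans(X)
  xs <- apply(X, 2L, stats::sd)
  xs[xs < 1e-12] <- 1
  Xs <- scale(X, center = xm, scale = xs)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  # response standardized as well: the (c, g) exponent grid and the
  # epsilon tube are defined on the analyte's scaled axis
  ym <- mean(y); ysd <- stats::sd(y)
  ys <- (y - ym) / ysd
  folds <- cv_folds(n, n_folds, seed)
  to_lin <- function(v) if (grid_linear) v else 2^v
  grid <- expand.grid(c = c_grid, g = g_grid, KEEP.OUT.ATTRS = FALSE)
  cv_rmse <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    C <- to_lin(grid$c[r]); gam <- to_lin(grid$g[r])
    sse <- 0
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      fit <- e1071::svm(Xs[tr, , drop = FALSE], ys[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = C, gamma = gam, epsilon = epsilon,
                        scale = FALSE)
      pred <- ym + ysd * stats::predict(fit, Xs[!tr, , drop = FALSE])
      sse <- sse + sum((pred - y[!tr])^2)
    }
    cv_rmse[r] <- sqrt(sse / n)
  }
  grid$cv_rmse <- cv_rmse
  best <- order(cv_rmse, grid$c, grid$g)[1L]  # ties: smaller C, then gamma
  C <- to_lin(grid$c[best]); gam <- to_lin(grid$g[best])
  # tighter optimizer tolerance on the final refit so the epsilon-tube
  # property holds to near machine precision on separable data
  fit <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gam, epsilon = epsilon, scale = FALSE,
                    tolerance = 1e-8)
  structure(list(c = grid$c[best], g = grid$g[best], cost = C, gamma = gam,
                 epsilon = epsilon, grid_linear = grid_linear,
                 support_vectors = unname(as.matrix(fit$SV)),
                 dual_coefs = as.numeric(fit$coefs), rho = fit$rho,
                 x_means = xm, x_scales = xs,
                 y_center = ym, y_scale = ysd, cv_table = grid,
                 subset = if (is.null(subset)) seq_len(ncol(X)) else as.integer(subset),
                 n_full = if (is.null(n_full)) ncol(X) else as.integer(n_full),
                 fitted_values = NULL),
            class = "svr_model") -> m
  m$fitted_values <- predict(m, X)
  m
}

#' Predict from an SVR calibration model
#'
#' Evaluates the decision function
#' `sum_i alpha_i exp(-gamma ||x - sv_i||^2) - rho` on autoscaled input
#' and maps it back to concentration units. Accepts the training
#' wavelength subset or the full grid.
#'
#' @param object an `svr_model`.
#' @param newdata numeric matrix (or [spectra_set()]).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- as_matrix_x(newdata)
  X <- slice_to_subset(X, object)
  Xs <- scale(X, center = object$x_means, scale = object$x_scales)
  SV <- object$support_vectors
  d2 <- outer(rowSums(Xs^2), rowSums(SV^2), "+") - 2 * Xs %*% t(SV)
  d2[d2 < 0] <- 0
  raw <- exp(-object$gamma * d2) %*% object$dual_coefs - object$rho
  as.numeric(object$y_center + object$y_scale * raw)
}

#' @export
print.svr_model <- function(x, ...) {
  cat("RBF-SVR calibration model: c = ", format(x$c), ", g = ", format(x$g),
      if (!x$grid_linear) " (log2)", ", ", nrow(x$support_vectors),
      " support vectors, ", length(x$subset), " wavelengths\n", sep = "")
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' Both model classes round-trip exactly: predictions from the reloaded
#' model equal predictions from the original.
#'
#' @param m a `plsr_model` or `svr_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model_json <- function(m, path) {
  cls <- class(m)[1L]
  if (!cls %in% c("plsr_model", "svr_model")) {
    stop_nircal("unsupported model class '", cls, "'")
  }
  payload <- unclass(m)
  payload$.class <- cls
  if (cls == "svr_model") payload$cv_table <- as.list(payload$cv_table)
  if (cls == "plsr_model") payload$cv <- lapply(payload$cv, unname)
  # digits = I(17): 17 significant digits, exact double round-trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' @param path path written by [save_model_json()].
#' @return The restored model object.
#' @export
load_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  for (f in c("subset", "n_full", "n_latent_variables")) {
    if (!is.null(payload[[f]])) payload[[f]] <- as.integer(payload[[f]])
  }
  if (cls == "svr_model") {
    payload$cv_table <- as.data.frame(payload$cv_table)
    payload$support_vectors <- as.matrix(payload$support_vectors)
  }
  structure(payload, class = cls)
}
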