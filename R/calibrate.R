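# The end-to-end calibration pipeline as a single model-fitting function.
# Stage order (leak-free by construction): split -> fit preprocessor on
# calibration rows, apply to both blocks -> select wavelengths on the
# calibration block only -> fit the calibration model -> evaluate.
# Every stage's seed is derived from the master seed with a stable label
# hash, so reruns are bit-identical and stages are independent.

#' Fit an NIR calibration pipeline
#'
#' Splits the samples into calibration and prediction sets, pretreats the
#' spectra (preprocessor state fitted on the calibration block only),
#' optionally selects wavelengths with CARS or random frog, fits a PLSR or
#' RBF-SVR calibration model, and evaluates Rc/RMSEC on the calibration
#' set and Rp/RMSEP on the prediction set. The prediction block never
#' enters preprocessing state, selection or fitting.
#'
#' @param spectra a [spectra_set()].
#' @param concentrations a paired [concentration_table()].
#' @param preprocess one of `"none"`, `"snv"`, `"msc"`, `"norm"`, `"sg"`.
#' @param selector one of `"none"`, `"cars"`, `"frog"`.
#' @param model one of `"plsr"`, `"svr"`.
#' @param split_ratio calibration fraction (default 0.7, the usual 7:3).
#' @param seed master seed; all stage seeds derive from it.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param cars a [cars_params()]; its `seed` is overridden by the derived
#'   stage seed.
#' @param frog a [frog_params()]; likewise.
#' @param max_lv,n_folds PLSR latent-variable search settings.
#' @param svr_epsilon,svr_folds,c_grid,g_grid SVR grid-search settings.
#' @return An object of class `nir_calibration` with components `split`,
#'   `preprocessor`, `selection` (or `NULL`), `model`, `metrics` and the
#'   configuration; supports `print`, `summary`, `coef`, `predict`,
#'   `residuals` and `plot`.
#' @export
#' @examples
#' sim <- simulate_dataset(default_milk_powder_config(
#'   "Vc", n_points = 120, n_samples = 40, seed = 9))
#' fit <- nir_calibrate(sim$spectra, sim$reference, preprocess = "snv",
#'                      n_folds = 5, seed = 9)
#' fit
#' predict(fit, sim$spectra)[1:3]
nir_calibrate <- function(spectra, concentrations,
                          preprocess = c("none", "snv", "msc", "norm", "sg"),
                          selector = c("none", "cars", "frog"),
                          model = c("plsr", "svr"),
                          split_ratio = 0.7, seed = 1L,
                          sg_window = 11L, sg_order = 2L,
                          cars = cars_params(), frog = frog_params(),
                          max_lv = 10L, n_folds = 10L,
                          svr_epsilon = 0.01, svr_folds = 5L,
                          c_grid = seq(-10, 10, by = 0.5),
                          g_grid = seq(-10, 10, by = 0.5)) {
  preprocess <- match.arg(preprocess)
  selector <- match.arg(selector)
  model <- match.arg(model)
  y_all <- pair_xy(spectra, concentrations)
  split <- split_calibration_prediction(spectra, concentrations, split_ratio,
                                        seed = derive_seed(seed, "split"))
  X <- spectra$absorbance
  X_cal <- X[split$calibration, , drop = FALSE]
  X_pred <- X[split$prediction, , drop = FALSE]
  y_cal <- y_all[split$calibration]
  y_pred <- y_all[split$prediction]
  pp <- fit_preprocessor(preprocess, X_cal, sg_window = sg_window,
                         sg_order = sg_order)
  P_cal <- apply_preprocessor(pp, X_cal)
  P_pred <- apply_preprocessor(pp, X_pred)
  n_folds <- min(n_folds, nrow(P_cal))
  sel <- switch(selector,
    none = NULL,
    cars = {
      cars$seed <- derive_seed(seed, "select", "cars")
      cars_select(P_cal, y_cal, cars)
    },
    frog = {
      frog$seed <- derive_seed(seed, "select", "frog")
      random_frog_select(P_cal, y_cal, frog)
    })
  idx <- if (is.null(sel)) seq_len(ncol(X)) else sel$selected_indices
  fit_seed <- derive_seed(seed, "fit", model)
  m <- if (model == "plsr") {
    fit_plsr(P_cal[, idx, drop = FALSE], y_cal, max_lv = max_lv,
             n_folds = n_folds, seed = fit_seed,
             subset = idx, n_full = ncol(X))
  } else {
    fit_svr_grid(P_cal[, idx, drop = FALSE], y_cal, c_grid = c_grid,
                 g_grid = g_grid, epsilon = svr_epsilon,
                 n_folds = min(svr_folds, nrow(P_cal)), seed = fit_seed,
                 subset = idx, n_full = ncol(X))
  }
  metrics <- evaluate_fit(m, P_cal, y_cal, P_pred, y_pred,
                          cal_ids = spectra$sample_ids[split$calibration],
                          pred_ids = spectra$sample_ids[split$prediction],
                          meta = list(analyte = concentrations$analyte,
                                      preprocess = preprocess,
                                      selector = selector, model = model,
                                      n_selected = length(idx), seed = seed))
  structure(list(call = match.call(),
                 config = list(analyte = concentrations$analyte,
                               preprocess = preprocess, selector = selector,
                               model = model, split_ratio = split_ratio,
                               seed = as.integer(seed)),
                 wavenumbers = spectra$wavenumbers,
                 split = split, preprocessor = pp, selection = sel,
                 model = m, metrics = metrics,
                 y = list(calibration = y_cal, prediction = y_pred),
                 units = concentrations$units),
            class = "nir_calibration")
}

#' @export
print.nir_calibration <- function(x, ...) {
  cat("NIR calibration pipeline (seed ", x$config$seed, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
summary.nir_calibration <- function(object, ...) {
  x <- object
  cat("NIR calibration of ", x$config$analyte, "\n", sep = "")
  cat("  split: ", length(x$split$calibration), " calibration / ",
      length(x$split$prediction), " prediction (ratio ",
      format(x$config$split_ratio), ")\n", sep = "")
  cat("  preprocessing: ", x$config$preprocess, "\n", sep = "")
  if (!is.null(x$selection)) {
    cat("  selector: ", x$selection$method, ", ",
        length(x$selection$selected_indices), " of ", x$selection$n_total,
        " wavelengths (reduction ",
        reduction_percent(length(x$selection$selected_indices),
                          x$selection$n_total), "%)\n", sep = "")
  } else {
    cat("  selector: none (full spectrum, ", length(x$wavenumbers),
        " wavelengths)\n", sep = "")
  }
  if (inherits(x$model, "plsr_model")) {
    cat("  model: PLSR, ", x$model$n_latent_variables,
        " latent variables\n", sep = "")
  } else {
    cat("  model: RBF-SVR, c = ", format(x$model$c), ", g = ",
        format(x$model$g), if (!x$model$grid_linear) " (log2)", "\n",
        sep = "")
  }
  print(x$metrics)
  invisible(x)
}

#' @export
coef.nir_calibration <- function(object, ...) coef(object$model)

#' @export
coef.svr_model <- function(object, ...) {
  list(dual_coefs = object$dual_coefs, rho = object$rho,
       cost = object$cost, gamma = object$gamma)
}

#' Predict analyte concentrations for new spectra
#'
#' Applies the stored preprocessor, then the fitted model (which slices
#' to its wavelength subset internally).
#'
#' @param object a fitted `nir_calibration`.
#' @param newdata a [spectra_set()] or absorbance matrix on the training
#'   grid.
#' @param ... unused.
#' @return Named numeric vector of predicted concentrations.
#' @export
predict.nir_calibration <- function(object, newdata, ...) {
  ids <- if (inherits(newdata, "spectra_set")) newdata$sample_ids else rownames(newdata)
  X <- apply_preprocessor(object$preprocessor, as_matrix_x(newdata))
  stats::setNames(predict(object$model, X), ids)
}

#' @export
residuals.nir_calibration <- function(object, ...) {
  object$y$calibration - object$model$fitted_values
}

#' Predicted-versus-measured plot for a calibration
#'
#' Scatter of predicted against reference concentrations for both sets,
#' with the identity line.
#'
#' @param x a fitted `nir_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nir_calibration <- function(x, ...) {
  yc <- x$y$calibration
  yc_hat <- x$model$fitted_values
  graphics::plot(yc, yc_hat, pch = 1,
                 xlab = paste0("Reference (", x$units, ")"),
                 ylab = paste0("Predicted (", x$units, ")"),
                 main = sprintf("%s: Rc %.3f, Rp %.3f", x$config$analyte,
                                x$metrics$Rc, x$metrics$Rp), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Benchmark pipeline configurations over analytes and seeds
#'
#' Simulates a dataset per (analyte, replicate) and runs every pipeline
#' configuration on the same data, so configurations are compared
#' like-for-like; reports the per-seed metrics and the median over seeds
#' per cell. Per-cell seeds derive from the master seed by a stable hash
#' of the configuration labels, so adding a configuration never shifts
#' another's results.
#'
#' @param analytes character vector of analyte labels for
#'   [default_milk_powder_config()].
#' @param configs list of configuration lists with elements `preprocess`,
#'   `selector`, `model` (and optionally `label`).
#' @param n_seeds number of replicate seeds (>= 1).
#' @param master_seed master seed.
#' @param sim_overrides named list of overrides passed to
#'   [default_milk_powder_config()] (e.g. smaller grids for quick runs).
#' @param ... further arguments passed to [nir_calibrate()].
#' @return An object of class `benchmark_table` with `$results` (one row
#'   per analyte x config x seed) and `$summary` (medians over seeds).
#' @export
benchmark_table <- function(analytes, configs, n_seeds = 10L,
                            master_seed = 1L, sim_overrides = list(), ...) {
  if (n_seeds < 1L) stop_nircal("need at least one seed")
  rows <- list()
  for (an in analytes) {
    for (r in seq_len(n_seeds)) {
      data_seed <- derive_seed(master_seed, "data", an, r)
      cfg <- do.call(default_milk_powder_config,
                     c(list(analyte = an), sim_overrides))
      sim <- simulate_dataset(cfg, seed = data_seed)
      for (cf in configs) {
        label <- cf$label %||% paste(cf$preprocess, cf$selector, cf$model,
                                     sep = "-")
        run_seed <- derive_seed(master_seed, "run", an, r, label)
        fit <- nir_calibrate(sim$spectra, sim$reference,
                             preprocess = cf$preprocess,
                             selector = cf$selector, model = cf$model,
                             seed = run_seed, ...)
        row <- as.data.frame(fit$metrics)
        row$config <- label
        row$replicate <- r
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(results[, c("n_selected", "Rc", "RMSEC", "Rp", "RMSEP")],
                          by = list(analyte = results$analyte,
                                    config = results$config),
                          FUN = stats::median)
  structure(list(results = results, summary = agg,
                 master_seed = as.integer(master_seed), n_seeds = n_seeds),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, digits = 4, ...) {
  cat("Benchmark over", x$n_seeds, "seeds (medians per cell):\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Render a benchmark summary as a Markdown table
#'
#' Columns mirror the usual calibration comparison layout: method,
#' number of characteristic wavelengths, Rc, RMSEC, Rp, RMSEP.
#'
#' @param x a `benchmark_table`.
#' @param digits significant digits.
#' @return Character vector of Markdown lines.
#' @export
format_markdown <- function(x, digits = 4) {
  stopifnot(inherits(x, "benchmark_table"))
  s <- x$summary
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  c("| Analyte | Method | Wavelengths | Rc | RMSEC | Rp | RMSEP |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s |", s$analyte, s$config,
            fmt(s$n_selected), fmt(s$Rc), fmt(s$RMSEC), fmt(s$Rp),
            fmt(s$RMSEP)))
}
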