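# Evaluation metrics: Rc/RMSEC on the calibration set, Rp/RMSEP on the
# prediction set. Rc/Rp are Pearson correlations between reference and
# predicted values (the usual "related coefficient" of NIR calibration
# reports, not R^2).

#' Pearson correlation between reference and predicted values
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2, neither
#'   constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_nircal("length mismatch")
  if (length(y_true) < 2L) stop_nircal("need at least 2 values")
  if (stats::sd(y_true) <= 0 || stats::sd(y_pred) <= 0) {
    stop_nircal("correlation undefined for a constant vector")
  }
  stats::cor(y_true, y_pred)
}

#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal length >= 1.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_nircal("length mismatch")
  if (length(y_true) < 1L) stop_nircal("empty input")
  sqrt(mean((y_true - y_pred)^2))
}

#' Evaluate a fitted calibration model on both sets
#'
#' Computes Rc/RMSEC on the calibration block and Rp/RMSEP on the
#' prediction block. If sample ids are supplied for both blocks, any
#' overlap is an error (leak guard).
#'
#' @param model a fitted `plsr_model` or `svr_model`.
#' @param X_cal,y_cal calibration block.
#' @param X_pred,y_pred prediction block.
#' @param cal_ids,pred_ids optional sample ids used for the disjointness
#'   check.
#' @param meta optional named list of pipeline metadata (analyte,
#'   preprocessing, selector, model label, n_selected, seed) copied into
#'   the report.
#' @return An object of class `metrics_report` with fields `Rc`, `RMSEC`,
#'   `Rp`, `RMSEP` plus the metadata.
#' @export
evaluate_fit <- function(model, X_cal, y_cal, X_pred, y_pred,
                         cal_ids = NULL, pred_ids = NULL, meta = list()) {
  if (!is.null(cal_ids) && !is.null(pred_ids) &&
      length(intersect(cal_ids, pred_ids))) {
    stop_nircal("calibration and prediction sets overlap: ",
                paste(utils::head(intersect(cal_ids, pred_ids), 3L),
                      collapse = ", "))
  }
  yc_hat <- predict(model, X_cal)
  yp_hat <- predict(model, X_pred)
  rep <- list(analyte = meta$analyte %||% NA_character_,
              preprocess = meta$preprocess %||% NA_character_,
              selector = meta$selector %||% NA_character_,
              model = meta$model %||% class(model)[1L],
              n_selected = meta$n_selected %||% length(model$subset),
              seed = meta$seed %||% NA_integer_,
              Rc = pearson_r(y_cal, yc_hat), RMSEC = rmse(y_cal, yc_hat),
              Rp = pearson_r(y_pred, yp_hat), RMSEP = rmse(y_pred, yp_hat))
  structure(rep, class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("%s | pre: %s | sel: %s (%d wl) | model: %s\n",
              x$analyte, x$preprocess, x$selector, x$n_selected, x$model))
  cat(sprintf("  Rc = %.*f  RMSEC = %.*f  Rp = %.*f  RMSEP = %.*f\n",
              digits, x$Rc, digits, x$RMSEC, digits, x$Rp, digits, x$RMSEP))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(analyte = x$analyte, preprocess = x$preprocess,
             selector = x$selector, model = x$model,
             n_selected = x$n_selected, seed = x$seed,
             Rc = x$Rc, RMSEC = x$RMSEC, Rp = x$Rp, RMSEP = x$RMSEP,
             stringsAsFactors = FALSE)
}
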