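#' Root mean square error
#'
#' `sqrt(mean((y - y_hat)^2))`.
#'
#' @param y Reference values.
#' @param y_hat Predicted values, same length.
#' @return A non-negative scalar in the units of `y`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("rmse: length mismatch")
  sqrt(mean((y - y_hat)^2))
}

#' Mean absolute error
#'
#' `mean(abs(y - y_hat))`.
#'
#' @inheritParams rmse
#' @return A non-negative scalar in the units of `y`.
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("mae: length mismatch")
  mean(abs(y - y_hat))
}

#' Coefficient of determination
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`; may be negative for
#' predictions worse than the reference mean.
#'
#' @inheritParams rmse
#' @return A scalar `<= 1`.
#' @export
r2 <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("r2: length mismatch")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r2: undefined for zero-variance reference")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Bundle the three evaluation metrics
#'
#' @param rmse,mae,r2 Metric values (see [rmse()], [mae()], [r2()]).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(rmse, mae, r2) {
  stopifnot(rmse >= 0, mae >= 0, rmse >= mae - 1e-12, r2 <= 1 + 1e-12)
  structure(list(rmse = rmse, mae = mae, r2 = r2), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> RMSE %.4f  MAE %.4f  R2 %.4f\n",
              x$rmse, x$mae, x$r2))
  invisible(x)
}

#' Preprocessing improvement deltas
#'
#' Relative improvements of the preprocessed-input run over the raw-input run:
#' `dRMSE% = 100 * (RMSE_s - RMSE_x) / RMSE_s`,
#' `dMAE%  = 100 * (MAE_s  - MAE_x)  / MAE_s`,
#' `dR2    = R2_x - R2_s` (signed difference, not a percentage),
#' where subscript `s` is the raw run and `x` the preprocessed run.
#'
#' @param raw_report [eval_report()] for the raw (1-channel) input.
#' @param prep_report [eval_report()] for the preprocessed (7-channel) input.
#' @return A list with `delta_rmse_pct`, `delta_mae_pct`, `delta_r2`.
#' @export
delta_metrics <- function(raw_report, prep_report) {
  stopifnot(inherits(raw_report, "eval_report"),
            inherits(prep_report, "eval_report"))
  if (raw_report$rmse <= 0 || raw_report$mae <= 0)
    stop("delta_metrics: raw RMSE and MAE must be positive")
  list(delta_rmse_pct = 100 * (raw_report$rmse - prep_report$rmse) / raw_report$rmse,
       delta_mae_pct = 100 * (raw_report$mae - prep_report$mae) / raw_report$mae,
       delta_r2 = prep_report$r2 - raw_report$r2)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between predictions and a reference: differences
#' `d = prediction - reference`, `bias = mean(d)`, `sd = sd(d)` (denominator
#' `n - 1`), 95% limits of agreement `bias +/- 1.96 * sd`. Per-point
#' `(mean, difference)` pairs are returned for plotting.
#'
#' @param reference Reference signal values.
#' @param prediction Predicted values, same length (>= 2).
#' @return An object of class `bland_altman` with `bias`, `sd`, `loa_low`,
#'   `loa_high`, `means`, `diffs`.
#' @export
bland_altman <- function(reference, prediction) {
  if (length(reference) != length(prediction))
    stop("bland_altman: length mismatch")
  if (length(reference) < 2L) stop("bland_altman: need at least 2 points")
  d <- prediction - reference
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 means = (prediction + reference) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, SD %.3f, 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 16, cex = 0.4,
                 xlab = "Mean of prediction and reference",
                 ylab = "Prediction - reference", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Evaluate a trained model on a held-out paired record
#'
#' Runs the full inference path: build the feature matrix from the source
#' trace (unless one is supplied), z-score with the training-fitted
#' normalizer, slice into sliding windows, forward through the model, fuse
#' overlapping window predictions, invert the normalization, and compute
#' RMSE/MAE/R-squared plus a Bland-Altman analysis against the target over
#' the covered sample range.
#'
#' @param model A trained [init_cbanet()] model.
#' @param record A [paired_record()] longer than the window.
#' @param norm The [fit_normalizer()] fitted on training data.
#' @param spec A [window_spec()].
#' @param features Optional precomputed feature matrix for `record$source`.
#' @param hr_range_bpm Passed to [build_feature_matrix()] when features are
#'   computed here.
#' @return A list with `report` ([eval_report()]), `bland_altman`,
#'   `prediction` (denormalized, `NA` where uncovered) and `covered`.
#' @export
evaluate_pipeline <- function(model, record, norm, spec,
                              features = NULL, hr_range_bpm = c(40, 180)) {
  stopifnot(inherits(record, "paired_record"), inherits(norm, "normalizer"),
            inherits(spec, "window_spec"))
  if (is.null(features)) {
    features <- build_feature_matrix(record$source, hr_range_bpm = hr_range_bpm)
    features <- as.matrix(unclass(features))[, seq_len(model$config$in_channels),
                                             drop = FALSE]
  }
  xn <- normalize_data(norm, x = features)
  win <- make_windows(xn, spec)
  preds <- lapply(win$windows, cbanet_forward, model = model)
  fused <- fuse_overlapping(preds, win$starts, nrow(xn), spec)
  y_hat <- denormalize_target(norm, fused$prediction)
  idx <- which(fused$covered)
  y <- record$target$samples[idx]
  rep <- eval_report(rmse(y, y_hat[idx]), mae(y, y_hat[idx]), r2(y, y_hat[idx]))
  list(report = rep, bland_altman = bland_altman(y, y_hat[idx]),
       prediction = y_hat, covered = fused$covered)
}
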