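# Regression metrics for percent-inhibition prediction, including the
# composite score 0.5 * (1 - NRMSE) + 0.5 * PCC that balances absolute
# accuracy against preservation of the relative inhibition ranking.

check_pair <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y)) {
    abort2("y and yhat must be non-empty vectors of equal length",
           "cyp3a4hybrid_metric_error")
  }
}

#' Root-mean-square error
#' @param y,yhat Observed and predicted values (percentage points).
#' @return RMSE in percentage points.
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation between observations and predictions
#'
#' Errors on constant input, where the correlation is undefined.
#' @param y,yhat Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 2L) abort2("need at least 2 observations", "cyp3a4hybrid_metric_error")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    abort2("correlation undefined for constant input", "cyp3a4hybrid_metric_error")
  }
  stats::cor(y, yhat)
}

#' Coefficient of determination
#' @param y,yhat Observed and predicted values.
#' @return `1 - SS_res / SS_tot`; negative for worse-than-mean predictors.
#' @export
r2 <- function(y, yhat) {
  check_pair(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort2("R^2 undefined for constant y", "cyp3a4hybrid_metric_error")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Composite metric from precomputed error and correlation
#'
#' `0.5 * (1 - rmse_value / label_range) + 0.5 * pcc_value`. The label
#' range defaults to 100 since curated labels live on the closed 0-100
#' percent scale.
#'
#' @param rmse_value Nonnegative RMSE in percentage points.
#' @param pcc_value Pearson correlation.
#' @param label_range Normalization constant (percentage points, > 0).
#' @param weights Length-2 nonnegative weights for the error and
#'   correlation components (default equal).
#' @return Dimensionless composite score, at most 1.
#' @export
custom_metric_from_components <- function(rmse_value, pcc_value,
                                          label_range = 100,
                                          weights = c(0.5, 0.5)) {
  stopifnot(rmse_value >= 0, label_range > 0, length(weights) == 2L,
            all(weights >= 0))
  weights[[1]] * (1 - rmse_value / label_range) + weights[[2]] * pcc_value
}

#' Composite metric from raw prediction vectors
#' @inheritParams pcc
#' @inheritParams custom_metric_from_components
#' @return Dimensionless composite score.
#' @export
custom_metric <- function(y, yhat, label_range = 100, weights = c(0.5, 0.5)) {
  custom_metric_from_components(rmse(y, yhat), pcc(y, yhat), label_range, weights)
}

#' Full evaluation report for a prediction set
#'
#' @inheritParams pcc
#' @param label_range Either a positive number (default 100) or the string
#'   `"empirical"` to use `max(y) - min(y)`.
#' @return An `eval_report` list: `n`, `rmse`, `nrmse`, `r2`, `pcc`,
#'   `custom_metric`, `label_range`.
#' @export
eval_report <- function(y, yhat, label_range = 100) {
  check_pair(y, yhat)
  if (identical(label_range, "empirical")) label_range <- diff(range(y))
  stopifnot(is.numeric(label_range), label_range > 0)
  e <- rmse(y, yhat)
  p <- pcc(y, yhat)
  structure(list(n = length(y), rmse = e, nrmse = e / label_range,
                 r2 = r2(y, yhat), pcc = p,
                 custom_metric = custom_metric_from_components(e, p, label_range),
                 label_range = label_range),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n = %d\n  RMSE  %8.4f  (NRMSE %.4f, range %g)\n",
                     "  R2    %8.4f\n  PCC   %8.4f\n  Custom Metric %.4f\n"),
              x$n, x$rmse, x$nrmse, x$label_range, x$r2, x$pcc, x$custom_metric))
  invisible(x)
}
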