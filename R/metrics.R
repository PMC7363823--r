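#' Root mean square error
#'
#' \eqn{RMSE(y, y') = \sqrt{\frac{1}{q}\sum_i (y_i - y'_i)^2}}.
#'
#' @param y_true,y_pred Numeric vectors of equal, non-zero length.
#' @return A non-negative scalar in the units of the inputs.
#' @export
rmse <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' Mean absolute error
#'
#' \eqn{MAE(y, y') = \frac{1}{q}\sum_i |y_i - y'_i|}. Always
#' \code{mae <= rmse} (power-mean inequality).
#'
#' @inheritParams rmse
#' @return A non-negative scalar.
#' @export
mae <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

check_metric_input <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  invisible(TRUE)
}

#' Signed prediction-error curves
#'
#' Per-point signed differences \eqn{y - y'}, the quantity plotted in
#' soft-sensor error curves. Use [utils::write.csv()] on the result to
#' export for plotting.
#'
#' @param y_true,y_pred Matrices of identical shape.
#' @return A matrix of the same shape.
#' @export
error_curves <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("error_curves: shape mismatch")
  }
  y_true - y_pred
}

metrics_report <- function(y_true, y_pred, label = "test") {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  outs <- colnames(y_true) %||% paste0("y", seq_len(ncol(y_true)))
  tab <- data.frame(
    output = outs,
    rmse = vapply(seq_len(ncol(y_true)), function(j) {
      rmse(y_true[, j], y_pred[, j])
    }, numeric(1)),
    mae = vapply(seq_len(ncol(y_true)), function(j) {
      mae(y_true[, j], y_pred[, j])
    }, numeric(1)))
  stopifnot(all(tab$rmse >= tab$mae - 1e-12), all(tab$mae >= 0))
  structure(list(table = tab, errors = error_curves(y_true, y_pred),
                 label = label),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Prediction metrics (", x$label, " split, g/L):\n", sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}
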