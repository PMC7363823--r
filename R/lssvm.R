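#' Single-output least-squares support vector machine
#'
#' Fits the classical LSSVM regressor: the inequality constraints of the SVM
#' are replaced by equalities with squared slack, so training reduces to one
#' (l + 1) x (l + 1) linear system
#' \deqn{\begin{pmatrix} 0 & 1_l^T \\ 1_l & K + g^{-1} I \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' with \eqn{K} the RBF Gram matrix of the training inputs. Kept as the
#' single-output baseline and limiting case of [mlssvm()].
#'
#' @param x An l x n matrix of (normalized) inputs.
#' @param y Numeric response of length l.
#' @param g Slack penalty, strictly positive.
#' @param sigma RBF kernel width, strictly positive.
#' @return An object of class \code{"lssvm"} with components
#'   \code{train_inputs}, \code{dual_coeffs} (\eqn{\alpha}, summing to zero),
#'   \code{bias}, \code{g} and \code{sigma}.
#' @examples
#' x <- matrix(seq(0, 1, length.out = 20))
#' fit <- lssvm(x, sin(2 * pi * x[, 1]), g = 100, sigma = 0.2)
#' predict(fit, matrix(c(0.25, 0.5)))
#' @export
lssvm <- function(x, y, g = 1, sigma = 1) {
  x <- as_points_matrix(x)
  y <- as.numeric(y)
  check_positive(g, "g")
  check_sigma(sigma)
  l <- nrow(x)
  if (length(y) != l) stop("lssvm: nrow(x) and length(y) differ")
  if (anyNA(x) || anyNA(y)) stop("lssvm: missing values in training data")

  K <- kernel_matrix(x, sigma = sigma)
  M <- rbind(c(0, rep(1, l)),
             cbind(1, K + diag(l) / g))
  sol <- tryCatch(
    solve(M, c(0, y)),
    error = function(e) {
      stop("lssvm: KKT system is singular or ill-conditioned (rcond = ",
           format(rcond(M), digits = 3), "); consider a smaller g or ",
           "different sigma", call. = FALSE)
    })
  structure(
    list(train_inputs = x,
         train_targets = y,
         dual_coeffs = sol[-1],
         bias = sol[1],
         g = g,
         sigma = sigma),
    class = "lssvm")
}

#' Predict from a fitted LSSVM
#'
#' Evaluates \eqn{\hat y(x) = \sum_i \alpha_i k(x, x_i) + b}.
#'
#' @param object A fitted \code{"lssvm"} object.
#' @param newdata A q x n matrix of query points.
#' @param ... Unused.
#' @return Numeric vector of length q.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  newdata <- as_points_matrix(newdata)
  if (ncol(newdata) != ncol(object$train_inputs)) {
    stop("predict.lssvm: newdata has ", ncol(newdata),
         " columns; model expects ", ncol(object$train_inputs))
  }
  kq <- kernel_matrix(newdata, object$train_inputs, sigma = object$sigma)
  drop(kq %*% object$dual_coeffs) + object$bias
}

#' @export
coef.lssvm <- function(object, ...) {
  list(dual_coeffs = object$dual_coeffs, bias = object$bias)
}

#' @export
residuals.lssvm <- function(object, ...) {
  # KKT identity: training residual y - yhat equals alpha / g
  object$dual_coeffs / object$g
}

#' @export
fitted.lssvm <- function(object, ...) {
  object$train_targets - residuals(object)
}

#' @export
print.lssvm <- function(x, ...) {
  cat("Least-squares SVM regressor\n")
  cat(sprintf("  training points: %d (dim %d)\n",
              nrow(x$train_inputs), ncol(x$train_inputs)))
  cat(sprintf("  g = %g, sigma = %g\n", x$g, x$sigma))
  invisible(x)
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
      value <= 0) {
    stop("'", name, "' must be a single positive number")
  }
  invisible(value)
}
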