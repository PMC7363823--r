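#' Gaussian (RBF) kernel between two vectors
#'
#' Computes \eqn{k(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))}, the radial
#' basis function kernel used throughout the package. The kernel width
#' \code{sigma} sets the length-scale on which two (normalized) process
#' states are considered similar.
#'
#' @param x,x_prime Numeric vectors of equal length.
#' @param sigma Kernel width, a strictly positive scalar.
#' @return A similarity in \eqn{(0, 1]}; exactly 1 when \code{x == x_prime}.
#' @seealso [kernel_matrix()]
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, x_prime, sigma) {
  check_sigma(sigma)
  x <- as.numeric(x)
  x_prime <- as.numeric(x_prime)
  if (length(x) != length(x_prime)) {
    stop("rbf_kernel: 'x' and 'x_prime' must have the same length (",
         length(x), " vs ", length(x_prime), ")")
  }
  exp(-sum((x - x_prime)^2) / (2 * sigma^2))
}

#' Kernel (Gram) matrix between two point sets
#'
#' Entry (i, j) is \code{rbf_kernel(a[i, ], b[j, ], sigma)}. Squared
#' Euclidean distances are computed with the usual
#' \eqn{\|a\|^2 + \|b\|^2 - 2 a^T b} expansion; when \code{b} is omitted the
#' result is symmetrized and given a unit diagonal to remove round-off
#' asymmetry, so it is a valid positive semidefinite Gram matrix.
#'
#' @param a A p x n numeric matrix (rows are points).
#' @param b A q x n numeric matrix; defaults to \code{a}.
#' @param sigma Kernel width, strictly positive.
#' @return A p x q matrix of kernel values.
#' @export
kernel_matrix <- function(a, b = NULL, sigma) {
  check_sigma(sigma)
  a <- as_points_matrix(a)
  square <- is.null(b)
  b <- if (square) a else as_points_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("kernel_matrix: point sets have different dimensions (",
         ncol(a), " vs ", ncol(b), ")")
  }
  k <- exp(-pairwise_sqdist(a, b) / (2 * sigma^2))
  if (square) {
    k <- (k + t(k)) / 2
    diag(k) <- 1
  }
  k
}

# squared Euclidean distances between rows of a and rows of b;
# negative round-off clipped at zero
pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

as_points_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1)
  storage.mode(x) <- "double"
  x
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("kernel width 'sigma' must be a single positive number")
  }
  invisible(sigma)
}
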