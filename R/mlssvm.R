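#' Multi-output least-squares support vector machine
#'
#' Fits an MLSSVM regressor mapping \eqn{R^n \to R^m}. Each output weight
#' vector is decomposed as a shared mean \eqn{w_0} plus a per-output contrast
#' \eqn{v_t}; the mean carries the correlation information between outputs and
#' the contrasts the differences. With the kernel trick the KKT conditions
#' reduce to the block linear system
#' \deqn{\begin{pmatrix} 0 & P^T \\ P & H \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0_m \\ y \end{pmatrix}, \quad
#'       H = \Omega + \gamma^{-1} I_{ml} + (m/\lambda) Q}
#' where \eqn{\Omega} tiles the Gram matrix \eqn{K} in every l x l block,
#' \eqn{Q} is block-diagonal with \eqn{K}, \eqn{P} is the block-diagonal
#' indicator of the m bias terms, and \eqn{y} stacks the output columns
#' (output-major). The system is solved by the positive-definite two-stage
#' route: \eqn{H\eta = P}, \eqn{Hv = y}, \eqn{S = P^T\eta},
#' \eqn{b = S^{-1}\eta^T y}, \eqn{\alpha = v - \eta b}.
#'
#' Because \eqn{H = (1_m 1_m^T) \otimes K + \gamma^{-1} I + (m/\lambda)
#' (I_m \otimes K)}, an orthogonal change of basis across the m outputs
#' block-diagonalizes \eqn{H} into one block \eqn{(m + m/\lambda) K +
#' \gamma^{-1} I} and m - 1 identical blocks \eqn{(m/\lambda) K +
#' \gamma^{-1} I}. The default solver (\code{method = "reduced"}) factorizes
#' those two l x l blocks once by Cholesky and reuses them for every
#' right-hand side; \code{method = "full"} assembles and factorizes the full
#' ml x ml system (same algebra, kept mainly for cross-checking). No jitter
#' beyond \eqn{\gamma^{-1} I} is ever applied: a factorization failure is an
#' error, so a hyperparameter search sees the true objective landscape.
#'
#' @param x An l x n matrix of (normalized) inputs, l >= 2.
#' @param y An l x m matrix of (normalized) targets.
#' @param gamma Slack penalty \eqn{\gamma > 0}.
#' @param lambda Output-contrast penalty \eqn{\lambda > 0}. Large
#'   \code{lambda} shrinks the contrasts, coupling the outputs; as
#'   \eqn{\lambda \to \infty} with m = 1 the model reduces to [lssvm()] with
#'   \code{g = gamma}.
#' @param sigma RBF kernel width \eqn{\sigma > 0}.
#' @param method \code{"reduced"} (default) or \code{"full"}; see Details.
#' @param refine Number of compensated-residual iterative-refinement steps
#'   applied to the solution (default 0). At strongly ill-conditioned
#'   hyperparameters (e.g. very large \code{gamma}) the forward error of any
#'   double-precision solve is limited by the conditioning of the KKT
#'   system; two or more refinement steps, with residuals accumulated in
#'   twice working precision, polish the solution to near machine accuracy.
#'   Refinement materializes the full system, so it is intended for
#'   moderate l.
#' @return An object of class \code{"mlssvm"}: \code{train_inputs},
#'   \code{dual_coeffs} (the l x m matrix A whose columns each sum to zero),
#'   \code{bias} (length m), and the hyperparameters.
#' @seealso [predict.mlssvm()], [assemble_mlssvm_system()], [solve_mlssvm()]
#' @examples
#' x <- matrix(runif(40), 20, 2)
#' y <- cbind(sin(3 * x[, 1]), x[, 1] * x[, 2])
#' fit <- mlssvm(x, y, gamma = 100, lambda = 1, sigma = 0.5)
#' colSums(coef(fit)$dual_coeffs)  # ~ 0: KKT condition A^T 1 = 0
#' @export
mlssvm <- function(x, y, gamma = 1, lambda = 1, sigma = 1,
                   method = c("reduced", "full"), refine = 0L) {
  method <- match.arg(method)
  if (refine > 0) method <- "full"
  x <- as_points_matrix(x)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  check_mlssvm_data(x, y)
  check_hyperparams(gamma, lambda, sigma)

  K <- kernel_matrix(x, sigma = sigma)
  sol <- if (method == "reduced") {
    mlssvm_solve_kernel(K, y, gamma, lambda)
  } else {
    solve_mlssvm(assemble_mlssvm_system(x, y, gamma, lambda, sigma),
                 refine = refine)
  }
  structure(
    list(train_inputs = x,
         train_targets = y,
         dual_coeffs = sol$dual_coeffs,
         bias = sol$bias,
         gamma = gamma,
         lambda = lambda,
         sigma = sigma,
         n_outputs = ncol(y)),
    class = "mlssvm")
}

#' Assemble the MLSSVM block KKT system
#'
#' Builds the full ml x ml matrix \eqn{H = \Omega + \gamma^{-1} I +
#' (m/\lambda) Q}, the ml x m bias indicator \eqn{P} and the output-major
#' stacked target vector. Mainly useful for inspection and cross-checks;
#' [mlssvm()] normally bypasses the explicit assembly.
#'
#' @inheritParams mlssvm
#' @return A list of class \code{"mlssvm_system"} with elements \code{H},
#'   \code{P}, \code{y_stacked}, \code{K}, \code{l}, \code{m},
#'   \code{gamma}, \code{lambda}.
#' @export
assemble_mlssvm_system <- function(x, y, gamma, lambda, sigma) {
  x <- as_points_matrix(x)
  y <- as.matrix(y)
  check_mlssvm_data(x, y)
  check_hyperparams(gamma, lambda, sigma)
  l <- nrow(y)
  m <- ncol(y)
  K <- kernel_matrix(x, sigma = sigma)
  omega <- matrix(1, m, m) %x% K
  Q <- diag(m) %x% K
  H <- omega + (m / lambda) * Q
  diag(H) <- diag(H) + 1 / gamma
  H <- (H + t(H)) / 2
  P <- diag(m) %x% matrix(1, l, 1)
  structure(
    list(H = H, P = P, y_stacked = as.vector(y), K = K,
         l = l, m = m, gamma = gamma, lambda = lambda),
    class = "mlssvm_system")
}

#' Solve an assembled MLSSVM system by the two-stage positive-definite route
#'
#' Solves \eqn{H\eta = P} and \eqn{Hv = y} from a single Cholesky
#' factorization of \eqn{H}, then \eqn{S = P^T \eta}, \eqn{b = S^{-1} \eta^T
#' y}, \eqn{\alpha = v - \eta b}. The returned dual coefficients are reshaped
#' output-major into an l x m matrix.
#'
#' @param system An \code{"mlssvm_system"} from [assemble_mlssvm_system()].
#' @param refine Number of compensated-residual refinement steps; see
#'   [mlssvm()].
#' @return List with \code{dual_coeffs} (l x m) and \code{bias} (length m).
#' @export
solve_mlssvm <- function(system, refine = 0L) {
  stopifnot(inherits(system, "mlssvm_system"))
  R <- tryCatch(
    chol(system$H),
    error = function(e) {
      stop("solve_mlssvm: H is not positive definite (Cholesky failed); ",
           "the hyperparameters give a numerically degenerate system",
           call. = FALSE)
    })
  m <- system$m
  # two-stage solve for a general right-hand side (c, y):
  # H eta = P, H v = y, S = P^T eta, b = S^-1 (eta^T y - c), a = v - eta b
  two_stage <- function(c_top, y_bot) {
    z <- backsolve(R, forwardsolve(t(R), cbind(system$P, y_bot)))
    eta <- z[, seq_len(m), drop = FALSE]
    v <- z[, m + 1]
    S <- crossprod(system$P, eta)
    S <- (S + t(S)) / 2
    b <- solve(S, crossprod(eta, y_bot) - c_top)
    list(b = as.numeric(b), alpha = as.numeric(v - eta %*% b))
  }
  sol <- two_stage(rep(0, m), system$y_stacked)
  if (refine > 0) {
    M <- rbind(cbind(matrix(0, m, m), t(system$P)),
               cbind(system$P, system$H))
    rhs <- c(rep(0, m), system$y_stacked)
    z <- c(sol$b, sol$alpha)
    for (s in seq_len(refine)) {
      r <- rhs - comp_matvec(M, z)
      d <- two_stage(r[seq_len(m)], r[-seq_len(m)])
      z <- z + c(d$b, d$alpha)
    }
    sol <- list(b = z[seq_len(m)], alpha = z[-seq_len(m)])
  }
  list(dual_coeffs = matrix(sol$alpha, system$l, system$m),
       bias = sol$b)
}

# matrix-vector product with elementwise Dekker two-product error terms and
# long-double row accumulation: residuals effectively in twice working
# precision, which is what lets iterative refinement beat the conditioning
# limit of a plain double-precision solve
comp_matvec <- function(M, x) {
  X <- matrix(x, nrow(M), length(x), byrow = TRUE)
  P <- M * X
  s <- 134217729  # 2^27 + 1, Dekker splitting constant
  cm <- s * M; mh <- cm - (cm - M); ml <- M - mh
  cx <- s * X; xh <- cx - (cx - X); xl <- X - xh
  E <- ((mh * xh - P) + mh * xl + ml * xh) + ml * xl
  rowSums(P) + rowSums(E)
}

# Two-stage solve exploiting the Kronecker structure of H (see ?mlssvm).
# K: l x l Gram matrix, Y: l x m targets. Returns dual_coeffs (l x m), bias.
mlssvm_solve_kernel <- function(K, Y, gamma, lambda) {
  l <- nrow(Y)
  m <- ncol(Y)
  # orthogonal U with first column 1/sqrt(m): diagonalizes 1_m 1_m^T
  U <- if (m == 1) matrix(1, 1, 1) else
    eigen(matrix(1, m, m), symmetric = TRUE)$vectors
  B0 <- (m / lambda) * K
  diag(B0) <- diag(B0) + 1 / gamma
  B1 <- B0 + m * K
  fail <- function(e) {
    stop("mlssvm: kernel system is not positive definite (Cholesky ",
         "failed); the hyperparameters give a numerically degenerate ",
         "system", call. = FALSE)
  }
  R1 <- tryCatch(chol(B1), error = fail)
  R0 <- if (m > 1) tryCatch(chol(B0), error = fail) else NULL
  spd_solve <- function(R, b) backsolve(R, forwardsolve(t(R), b))
  # solve H vec(C) for C given as l x m matrix, in the U basis per column
  solveH <- function(C) {
    Ct <- C %*% U
    Xt <- matrix(0, l, m)
    Xt[, 1] <- spd_solve(R1, Ct[, 1])
    if (m > 1) Xt[, -1] <- spd_solve(R0, Ct[, -1, drop = FALSE])
    Xt %*% t(U)
  }
  # eta column t solves H eta_t = vec(1_l e_t^T); collapse to two vectors
  s1 <- spd_solve(R1, rep(1, l))
  s0 <- if (m > 1) spd_solve(R0, rep(1, l)) else s1
  # E_t[, s] = s0 * [s == t] + (s1 - s0)/m  (from the rank-one structure)
  shared <- (s1 - s0) / m
  S <- diag(sum(s0), m) + sum(shared)
  S <- (S + t(S)) / 2
  eta_y <- crossprod(Y, s0) + sum(rowSums(Y) * shared)  # eta^T y, length m
  b <- as.numeric(solve(S, eta_y))
  V <- solveH(Y)
  A <- V - outer(s0, b) - outer(shared, rep(sum(b), m))
  list(dual_coeffs = A, bias = b)
}

#' Predict from a fitted MLSSVM
#'
#' Evaluates, for output t,
#' \eqn{\hat y_t(x) = \sum_j (\sum_i \alpha_{ij}) k(x, x_j) +
#' (m/\lambda) \sum_j \alpha_{jt} k(x, x_j) + b_t}:
#' a term shared across outputs (through the mean weight vector) plus a
#' per-output contrast term.
#'
#' @param object A fitted \code{"mlssvm"}.
#' @param newdata A q x n matrix of query points.
#' @param ... Unused.
#' @return A q x m matrix of predictions.
#' @export
predict.mlssvm <- function(object, newdata, ...) {
  newdata <- as_points_matrix(newdata)
  if (ncol(newdata) != ncol(object$train_inputs)) {
    stop("predict.mlssvm: newdata has ", ncol(newdata),
         " columns; model expects ", ncol(object$train_inputs))
  }
  kq <- kernel_matrix(newdata, object$train_inputs, sigma = object$sigma)
  mlssvm_predict_kernel(kq, object$dual_coeffs, object$bias, object$lambda)
}

# prediction from a precomputed query-vs-train kernel matrix
mlssvm_predict_kernel <- function(kq, A, b, lambda) {
  m <- ncol(A)
  shared <- drop(kq %*% rowSums(A))
  contrast <- (m / lambda) * (kq %*% A)
  sweep(contrast + shared, 2, b, "+")
}

#' @export
coef.mlssvm <- function(object, ...) {
  list(dual_coeffs = object$dual_coeffs, bias = object$bias)
}

#' @export
residuals.mlssvm <- function(object, ...) {
  # KKT identity A = gamma * Xi: training residuals Y - Yhat = A / gamma
  object$dual_coeffs / object$gamma
}

#' @export
fitted.mlssvm <- function(object, ...) {
  object$train_targets - residuals(object)
}

#' @export
print.mlssvm <- function(x, ...) {
  cat("Multi-output least-squares SVM regressor\n")
  cat(sprintf("  training points: %d (dim %d), outputs: %d\n",
              nrow(x$train_inputs), ncol(x$train_inputs), x$n_outputs))
  cat(sprintf("  gamma = %g, lambda = %g, sigma = %g\n",
              x$gamma, x$lambda, x$sigma))
  invisible(x)
}

check_mlssvm_data <- function(x, y) {
  if (!is.matrix(y)) stop("targets must be a matrix (l x m)")
  if (nrow(x) != nrow(y)) stop("inputs and targets have different row counts")
  if (nrow(x) < 2) stop("at least two training samples are required")
  if (ncol(x) < 1 || ncol(y) < 1) stop("empty input or output dimension")
  if (anyNA(x) || anyNA(y)) stop("missing values in training data")
  invisible(TRUE)
}

check_hyperparams <- function(gamma, lambda, sigma) {
  check_positive(gamma, "gamma")
  check_positive(lambda, "lambda")
  check_sigma(sigma)
  invisible(TRUE)
}
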