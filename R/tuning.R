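#' Sum-of-squared-errors tuning objective
#'
#' The fitness minimized by the hyperparameter search:
#' \eqn{f = \sum_i (y(i) - y'(i))^2} over all points and all outputs,
#' computed on the normalized scale so the three outputs contribute
#' comparably.
#'
#' @param y_true,y_pred Matrices (or vectors) of identical shape.
#' @return A non-negative scalar; equals \code{q * m * MSE}.
#' @export
sse_objective <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("sse_objective: shape mismatch between y_true and y_pred")
  }
  sum((y_true - y_pred)^2)
}

#' Hyperparameter search box (log2-exponent space)
#'
#' The continuous boxes \eqn{\gamma \in [2^{-5}, 2^{15}]},
#' \eqn{\lambda \in [2^{-10}, 2^{10}]}, \eqn{\sigma \in [2^{-15}, 2^3]},
#' expressed as exponent bounds. The search runs on the exponents
#' (dimension 3); candidate hyperparameters are \code{2^exponent}.
#'
#' @return A [search_space()] over \code{(log2 gamma, log2 lambda,
#'   log2 sigma)}.
#' @export
hyperparam_box <- function() {
  search_space(lower = c(-5, -10, -15), upper = c(15, 10, 3))
}

# Precompute everything reusable across fitness evaluations for
# leave-one-batch-out CV: normalized inputs/targets on the (optionally
# subsampled) time grid and squared-distance blocks per fold. Returns a
# closure hp -> total SSE that only exponentiates distances and runs the
# reduced SPD solve per fold. Failed factorizations yield a large finite
# penalty so the optimizer can keep moving.
make_cv_objective <- function(batches, subsample = 4, normalizer = NULL,
                              penalty = 1e12) {
  if (length(batches) < 2) {
    stop("leave-one-batch-out CV needs at least 2 batches")
  }
  np <- normalizer %||% fit_normalizer(batches)
  keep <- function(b) seq(1, length(b$time), by = subsample)
  xs <- lapply(batches, function(b) {
    normalize_aux(np, b$aux[keep(b), , drop = FALSE])
  })
  ys <- lapply(batches, function(b) {
    normalize_outputs(np, b$outputs[keep(b), , drop = FALSE])
  })
  x_all <- do.call(rbind, xs)
  y_all <- do.call(rbind, ys)
  fold_of <- rep(seq_along(batches), vapply(xs, nrow, 1L))
  d2_all <- pairwise_sqdist(x_all, x_all)
  folds <- lapply(seq_along(batches), function(f) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    list(d2_tr = d2_all[tr, tr], d2_te = d2_all[te, tr],
         y_tr = y_all[tr, , drop = FALSE], y_te = y_all[te, , drop = FALSE])
  })
  function(hp) {
    gamma <- hp$gamma; lambda <- hp$lambda; sigma <- hp$sigma
    total <- 0
    for (fold in folds) {
      sse <- tryCatch({
        K <- exp(-fold$d2_tr / (2 * sigma^2))
        sol <- mlssvm_solve_kernel(K, fold$y_tr, gamma, lambda)
        kq <- exp(-fold$d2_te / (2 * sigma^2))
        pred <- mlssvm_predict_kernel(kq, sol$dual_coeffs, sol$bias, lambda)
        sse_objective(fold$y_te, pred)
      }, error = function(e) penalty)
      if (!is.finite(sse)) sse <- penalty
      total <- total + sse
    }
    min(total, penalty)
  }
}

#' Leave-one-batch-out cross-validation objective
#'
#' For each batch in turn, fits an MLSSVM on the remaining batches and
#' accumulates the normalized-scale SSE of its predictions on the held-out
#' batch. Cross-validation is at the batch level because time points within
#' a batch are strongly correlated: holding out single samples would leak.
#' A failed factorization contributes a large finite penalty instead of an
#' exception, so an optimizer exploring extreme hyperparameters continues.
#'
#' @param hp List with \code{gamma}, \code{lambda}, \code{sigma}.
#' @param batches List of \code{"fermentation_batch"} objects (>= 2).
#' @param subsample Time-grid stride used for the CV fits (every k-th
#'   point; 1 = full grid). Default 4 (30-min spacing) keeps tuning cheap;
#'   the final model is refit on the full grid by [soft_sensor()].
#' @param normalizer Optional pre-fitted [fit_normalizer()]; fitted on
#'   \code{batches} when omitted.
#' @return The total SSE across folds (normalized scale).
#' @export
cv_objective <- function(hp, batches, subsample = 4, normalizer = NULL) {
  make_cv_objective(batches, subsample, normalizer)(hp)
}

#' Tune MLSSVM hyperparameters by metaheuristic search
#'
#' Minimizes [cv_objective()] over the log2-exponent box with one of the
#' optimizers: \code{"ics"} (improved cuckoo search, the default),
#' \code{"cs"} (standard cuckoo search), \code{"pso"} or \code{"ga"}.
#'
#' @param batches Training batches (>= 2).
#' @param box A [search_space()] over exponents; default [hyperparam_box()].
#' @param optimizer Optimizer name.
#' @param cfg A [cuckoo_config()] (population and budget settings are also
#'   used by the PSO/GA baselines).
#' @param seed Optional integer seed.
#' @param subsample,normalizer Passed to the CV objective.
#' @return List with \code{hyperparams} (gamma, lambda, sigma on the
#'   natural scale) and \code{result} (the \code{"optim_result"} trace).
#' @export
tune_hyperparameters <- function(batches, box = hyperparam_box(),
                                 optimizer = c("ics", "cs", "pso", "ga"),
                                 cfg = cuckoo_config(), seed = NULL,
                                 subsample = 4, normalizer = NULL) {
  optimizer <- match.arg(optimizer)
  cv <- make_cv_objective(batches, subsample, normalizer)
  objective <- function(e) cv(exponents_to_hp(e))
  runner <- switch(optimizer,
    ics = function(...) run_cuckoo(..., cfg = adjust_mode(cfg, "improved")),
    cs = function(...) run_cuckoo(..., cfg = adjust_mode(cfg, "standard")),
    pso = function(...) run_pso(..., cfg = cfg),
    ga = function(...) run_ga(..., cfg = cfg))
  result <- runner(objective, box, seed = seed)
  list(hyperparams = exponents_to_hp(result$best_position), result = result)
}

exponents_to_hp <- function(e) {
  list(gamma = 2^e[1], lambda = 2^e[2], sigma = 2^e[3])
}

adjust_mode <- function(cfg, mode) {
  cfg$mode <- mode
  cfg
}
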