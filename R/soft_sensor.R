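#' Fit a fermentation soft sensor
#'
#' End-to-end build of the soft-sensor model: a min-max normalizer is fitted
#' on the training batches; the MLSSVM hyperparameters (gamma, lambda,
#' sigma) are tuned by [tune_hyperparameters()] under leave-one-batch-out
#' CV on the (subsampled) training grid; optionally the tuning trace is
#' re-scored on the validation batches and the candidate with the smallest
#' validation SSE is selected ("model correction" by model selection, not
#' re-tuning); finally the MLSSVM is refit on the full 15-min grid of the
#' training batches. Validation and test batches never influence the
#' normalizer or the CV objective.
#'
#' @param train Training batches (list of \code{"fermentation_batch"},
#'   >= 2).
#' @param val Optional validation batches used for model correction and
#'   reported validation metrics.
#' @param optimizer One of \code{"ics"}, \code{"cs"}, \code{"pso"},
#'   \code{"ga"}.
#' @param cfg A [cuckoo_config()] controlling the search budget.
#' @param box Hyperparameter exponent box; default [hyperparam_box()].
#' @param subsample Time-grid stride for tuning-time fits (default 4);
#'   the final refit always uses the stride in \code{refit_subsample}.
#' @param refit_subsample Stride for the final refit (default 1: full
#'   grid).
#' @param correct Re-score distinct trace candidates on \code{val} and keep
#'   the validation-best (default: \code{TRUE} when \code{val} is given).
#' @param include_val Refit the final model on train + validation batches
#'   (default \code{FALSE}: train only).
#' @param seed Integer master seed for the tuning search.
#' @return An object of class \code{"soft_sensor"}: \code{model} (the
#'   fitted [mlssvm()]), \code{normalizer}, \code{hyperparams},
#'   \code{tuning} (the \code{"optim_result"}), \code{optimizer},
#'   \code{val_metrics} (per-output RMSE/MAE in g/L, when \code{val} given),
#'   \code{seed}.
#' @seealso [predict.soft_sensor()], [evaluate_soft_sensor()]
#' @export
soft_sensor <- function(train, val = NULL,
                        optimizer = c("ics", "cs", "pso", "ga"),
                        cfg = cuckoo_config(), box = hyperparam_box(),
                        subsample = 4, refit_subsample = 1,
                        correct = !is.null(val), include_val = FALSE,
                        seed = NULL) {
  optimizer <- match.arg(optimizer)
  if (length(train) < 2) stop("soft_sensor: need at least 2 training batches")
  np <- fit_normalizer(train)
  tuned <- tune_hyperparameters(train, box = box, optimizer = optimizer,
                                cfg = cfg, seed = seed,
                                subsample = subsample, normalizer = np)
  hp <- tuned$hyperparams

  if (isTRUE(correct) && length(val) > 0) {
    hp <- correct_on_validation(tuned$result, train, val, np, subsample) %||% hp
  }

  refit_batches <- if (isTRUE(include_val)) c(train, val) else train
  xy <- stack_batches(refit_batches, np, refit_subsample)
  model <- mlssvm(xy$x, xy$y, gamma = hp$gamma, lambda = hp$lambda,
                  sigma = hp$sigma)

  obj <- structure(
    list(model = model, normalizer = np, hyperparams = hp,
         tuning = tuned$result, optimizer = optimizer,
         subsample = subsample, seed = seed, val_metrics = NULL),
    class = "soft_sensor")
  if (length(val) > 0) {
    obj$val_metrics <- evaluate_soft_sensor(obj, val, label = "validation")
  }
  obj
}

# pick, among the distinct per-iteration best exponent vectors of the
# tuning trace, the one with smallest validation SSE (normalized scale)
correct_on_validation <- function(result, train, val, np, subsample) {
  cands <- unique(round(result$best_positions, 12))
  if (nrow(cands) == 0) return(NULL)
  xy_tr <- stack_batches(train, np, subsample)
  xy_va <- stack_batches(val, np, subsample)
  sse <- apply(cands, 1, function(e) {
    hp <- exponents_to_hp(e)
    tryCatch({
      fit <- mlssvm(xy_tr$x, xy_tr$y, gamma = hp$gamma, lambda = hp$lambda,
                    sigma = hp$sigma)
      sse_objective(xy_va$y, predict(fit, xy_va$x))
    }, error = function(e) Inf)
  })
  if (!any(is.finite(sse))) return(NULL)
  exponents_to_hp(cands[which.min(sse), ])
}

stack_batches <- function(batches, np, subsample = 1) {
  keep <- function(b) seq(1, length(b$time), by = subsample)
  x <- do.call(rbind, lapply(batches, function(b) {
    normalize_aux(np, b$aux[keep(b), , drop = FALSE])
  }))
  y <- do.call(rbind, lapply(batches, function(b) {
    normalize_outputs(np, b$outputs[keep(b), , drop = FALSE])
  }))
  list(x = x, y = y)
}

#' Predict concentrations from auxiliary inputs
#'
#' Normalizes the auxiliary inputs with the stored training ranges, runs
#' the MLSSVM, and inverts the output scaling, returning concentrations in
#' g/L.
#'
#' @param object A fitted \code{"soft_sensor"}.
#' @param newdata A q x 7 matrix with columns \code{T_C, pH, r_rpm, DO_pct,
#'   u1, u2, u3} (order or names), a \code{"fermentation_batch"}, or a list
#'   of batches.
#' @param ... Unused.
#' @return A q x 3 matrix with columns \code{X_gL, S_gL, P_gL}.
#' @export
predict.soft_sensor <- function(object, newdata, ...) {
  aux <- as_aux_matrix(newdata)
  xn <- normalize_aux(object$normalizer, aux)
  yn <- predict(object$model, xn)
  out <- denormalize_outputs(object$normalizer, yn)
  colnames(out) <- output_names
  out
}

as_aux_matrix <- function(newdata) {
  if (inherits(newdata, "fermentation_batch")) return(newdata$aux)
  if (is.list(newdata) && !is.data.frame(newdata) && !is.matrix(newdata)) {
    return(do.call(rbind, lapply(newdata, as_aux_matrix)))
  }
  aux <- as.matrix(newdata)
  if (ncol(aux) != length(aux_channel_names)) {
    stop("auxiliary inputs must have the 7 columns ",
         paste(aux_channel_names, collapse = ", "),
         " (got ", ncol(aux), " columns)")
  }
  if (!is.null(colnames(aux))) {
    missing <- setdiff(aux_channel_names, colnames(aux))
    if (length(missing)) {
      stop("auxiliary inputs are missing column(s): ",
           paste(missing, collapse = ", "))
    }
    aux <- aux[, aux_channel_names, drop = FALSE]
  }
  aux
}

#' Evaluate a soft sensor on held-out batches
#'
#' Predicts every batch and reports per-output RMSE and MAE in original
#' units (g/L), together with the signed error curves.
#'
#' @param object A fitted \code{"soft_sensor"}.
#' @param batches List of \code{"fermentation_batch"} objects.
#' @param label Split label stored in the report.
#' @return A list of class \code{"metrics_report"}: \code{table} (data
#'   frame with output, rmse, mae), \code{errors} (q x 3 signed error
#'   matrix, y - y'), \code{label}.
#' @export
evaluate_soft_sensor <- function(object, batches, label = "test") {
  if (inherits(batches, "fermentation_batch")) batches <- list(batches)
  y_true <- do.call(rbind, lapply(batches, function(b) b$outputs))
  y_pred <- predict(object, batches)
  metrics_report(y_true, y_pred, label = label)
}

#' @export
print.soft_sensor <- function(x, ...) {
  cat(sprintf("Fermentation soft sensor (%s-tuned MLSSVM)\n",
              toupper(x$optimizer)))
  cat(sprintf("  gamma = %.4g, lambda = %.4g, sigma = %.4g\n",
              x$hyperparams$gamma, x$hyperparams$lambda,
              x$hyperparams$sigma))
  cat(sprintf("  training points: %d, tuning evaluations: %d\n",
              nrow(x$model$train_inputs), x$tuning$evaluations))
  if (!is.null(x$val_metrics)) {
    cat("  validation RMSE (g/L):",
        paste(sprintf("%s %.4g", x$val_metrics$table$output,
                      x$val_metrics$table$rmse), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.soft_sensor <- function(object, ...) {
  print(object)
  cat("\nTuning trace (last 5 iterations):\n")
  tr <- object$tuning$trace
  print(utils::tail(tr, 5), row.names = FALSE)
  invisible(object)
}

#' Save / load a soft sensor as versioned JSON
#'
#' Serializes the support data, dual coefficients, bias, hyperparameters
#' and normalization ranges to a plain-text JSON archive
#' (\code{format_version} 1). The tuning trace is not stored.
#'
#' @param object A fitted \code{"soft_sensor"}.
#' @param path Output file path.
#' @return \code{write_soft_sensor} returns \code{path} invisibly;
#'   \code{read_soft_sensor} returns a \code{"soft_sensor"}.
#' @export
write_soft_sensor <- function(object, path) {
  stopifnot(inherits(object, "soft_sensor"))
  payload <- list(
    format_version = 1L,
    optimizer = object$optimizer,
    hyperparams = object$hyperparams,
    train_inputs = object$model$train_inputs,
    train_targets = object$model$train_targets,
    dual_coeffs = object$model$dual_coeffs,
    bias = object$model$bias,
    normalizer = unclass(object$normalizer))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_soft_sensor
#' @export
read_soft_sensor <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1) {
    stop("read_soft_sensor: unsupported archive version")
  }
  hp <- p$hyperparams
  model <- structure(
    list(train_inputs = as.matrix(p$train_inputs),
         train_targets = as.matrix(p$train_targets),
         dual_coeffs = as.matrix(p$dual_coeffs),
         bias = as.numeric(p$bias),
         gamma = hp$gamma, lambda = hp$lambda, sigma = hp$sigma,
         n_outputs = length(p$bias)),
    class = "mlssvm")
  np <- p$normalizer
  normalizer <- structure(
    list(aux_min = unlist(np$aux_min), aux_max = unlist(np$aux_max),
         out_min = unlist(np$out_min), out_max = unlist(np$out_max)),
    class = "ferm_normalizer")
  structure(
    list(model = model, normalizer = normalizer, hyperparams = hp,
         tuning = NULL, optimizer = p$optimizer, subsample = NA,
         seed = NA, val_metrics = NULL),
    class = "soft_sensor")
}
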