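#' Compare hyperparameter optimizers on a campaign
#'
#' Runs the full soft-sensor build ([soft_sensor()]) once per
#' (optimizer, seed) pair at matched evaluation budgets, evaluates each
#' fitted model on the held-out test batches, and tabulates per-output RMSE
#' and MAE (g/L) with per-optimizer medians. This reproduces the usual
#' soft-sensor benchmarking design: same data split, same budget, only the
#' tuner differs.
#'
#' @param campaign List of \code{"fermentation_batch"} objects.
#' @param split List with integer indices \code{train}, \code{val} (may be
#'   empty) and \code{test} into \code{campaign}.
#' @param optimizers Character vector among \code{"ics", "cs", "pso",
#'   "ga"} (>= 2).
#' @param cfg A [cuckoo_config()]; its population size and iteration budget
#'   apply to every optimizer.
#' @param seeds Integer seeds (>= 3); one soft sensor is fitted per
#'   optimizer and seed.
#' @param subsample Tuning-time grid stride; see [soft_sensor()].
#' @return An object of class \code{"optimizer_comparison"}: \code{rows}
#'   (one data-frame row per optimizer x seed with RMSE/MAE per output,
#'   tuned hyperparameters and evaluation counts) and \code{summary}
#'   (per-optimizer medians).
#' @export
compare_optimizers <- function(campaign,
                               split = list(train = 1:6, val = 7:8,
                                            test = 9:10),
                               optimizers = c("ics", "cs"),
                               cfg = cuckoo_config(n_nests = 12, n_max = 30),
                               seeds = 1:10, subsample = 4) {
  known <- c("ics", "cs", "pso", "ga")
  bad <- setdiff(optimizers, known)
  if (length(bad)) stop("unknown optimizer(s): ", paste(bad, collapse = ", "))
  if (length(optimizers) < 2) stop("need at least 2 optimizers to compare")
  if (length(seeds) < 3) stop("need at least 3 seeds")
  train <- campaign[split$train]
  val <- if (length(split$val)) campaign[split$val] else NULL
  test <- campaign[split$test]

  rows <- list()
  for (opt in optimizers) {
    for (s in seeds) {
      fit <- soft_sensor(train, val, optimizer = opt, cfg = cfg,
                         subsample = subsample, seed = s)
      rep <- evaluate_soft_sensor(fit, test, label = "test")
      tab <- rep$table
      rows[[length(rows) + 1]] <- data.frame(
        optimizer = opt, seed = s,
        rmse_X = tab$rmse[1], rmse_S = tab$rmse[2], rmse_P = tab$rmse[3],
        mae_X = tab$mae[1], mae_S = tab$mae[2], mae_P = tab$mae[3],
        gamma = fit$hyperparams$gamma, lambda = fit$hyperparams$lambda,
        sigma = fit$hyperparams$sigma,
        evaluations = fit$tuning$evaluations)
    }
  }
  rows <- do.call(rbind, rows)
  metric_cols <- c("rmse_X", "rmse_S", "rmse_P", "mae_X", "mae_S", "mae_P")
  summary <- do.call(rbind, lapply(split(rows, rows$optimizer), function(d) {
    cbind(data.frame(optimizer = d$optimizer[1], n_runs = nrow(d)),
          as.data.frame(lapply(d[metric_cols], stats::median)))
  }))
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary, split = split),
            class = "optimizer_comparison")
}

#' @export
print.optimizer_comparison <- function(x, ...) {
  cat("Optimizer comparison (median test metrics, g/L):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
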