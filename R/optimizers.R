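#' Cuckoo search configuration
#'
#' Settings for [run_cuckoo()] (and, for population size and budget, the
#' [run_pso()]/[run_ga()] baselines). In \code{mode = "improved"} the
#' discovery probability decays linearly from \code{pa_max} to \code{pa_min}
#' and the Levy step size decays geometrically from \code{step_max} to
#' \code{step_min} over the run, front-loading exploration and sharpening
#' local search in late iterations. In \code{mode = "standard"} the constants
#' \code{fixed_pa} and \code{fixed_step} are used throughout (the textbook
#' algorithm).
#'
#' @param n_nests Number of host nests (population size).
#' @param n_max Maximum number of iterations.
#' @param pa_max,pa_min Discovery-probability schedule endpoints,
#'   \code{0 < pa_min <= pa_max < 1}.
#' @param step_max,step_min Step-size schedule endpoints (positive; fractions
#'   of the search-box width).
#' @param levy_mu Levy tail exponent, in (1, 3).
#' @param mode \code{"improved"} (adaptive schedules) or \code{"standard"}.
#' @param fixed_pa,fixed_step Constants used in standard mode only. Defaults
#'   are the textbook discovery probability 0.25 and a fixed step equal to
#'   \code{step_max}.
#' @param tol Stop early once the best fitness is <= \code{tol}
#'   (default \code{-Inf}: run the full budget).
#' @param single_cuckoo If \code{TRUE}, only one randomly chosen nest
#'   generates a Levy proposal per iteration (a literal reading of the
#'   one-egg-per-cuckoo rule); default updates all nests each iteration.
#' @param literal_step_growth If \code{TRUE}, use the step schedule with
#'   \code{k = log(step_max/step_min)/n_max} so the step grows from
#'   \code{step_max}; the default decays it to \code{step_min}, which is the
#'   behaviour an adaptive fine-tuning schedule intends.
#' @return A list of class \code{"cuckoo_config"}.
#' @export
cuckoo_config <- function(n_nests = 24, n_max = 150,
                          pa_max = 0.5, pa_min = 0.05,
                          step_max = 0.5, step_min = 0.01,
                          levy_mu = 1.5,
                          mode = c("improved", "standard"),
                          fixed_pa = 0.25, fixed_step = step_max,
                          tol = -Inf,
                          single_cuckoo = FALSE,
                          literal_step_growth = FALSE) {
  mode <- match.arg(mode)
  if (n_nests < 2) stop("cuckoo_config: n_nests must be >= 2")
  if (n_max < 1) stop("cuckoo_config: n_max must be >= 1")
  if (!(pa_min > 0 && pa_min <= pa_max && pa_max < 1)) {
    stop("cuckoo_config: need 0 < pa_min <= pa_max < 1")
  }
  if (!(step_min > 0 && step_min <= step_max)) {
    stop("cuckoo_config: need 0 < step_min <= step_max")
  }
  if (!(levy_mu > 1 && levy_mu < 3)) {
    stop("cuckoo_config: levy_mu must lie in (1, 3)")
  }
  if (!(fixed_pa > 0 && fixed_pa < 1)) {
    stop("cuckoo_config: fixed_pa must lie in (0, 1)")
  }
  check_positive(fixed_step, "fixed_step")
  structure(
    list(n_nests = as.integer(n_nests), n_max = as.integer(n_max),
         pa_max = pa_max, pa_min = pa_min,
         step_max = step_max, step_min = step_min,
         levy_mu = levy_mu, mode = mode,
         fixed_pa = fixed_pa, fixed_step = fixed_step,
         tol = tol, single_cuckoo = isTRUE(single_cuckoo),
         literal_step_growth = isTRUE(literal_step_growth)),
    class = "cuckoo_config")
}

#' Box-constrained search space
#'
#' @param lower,upper Numeric vectors of equal length with
#'   \code{lower < upper} element-wise.
#' @return A list of class \code{"search_space"} with \code{lower},
#'   \code{upper}, \code{d}.
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) == 0) {
    stop("search_space: bounds must be non-empty vectors of equal length")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("search_space: need finite lower < upper element-wise")
  }
  structure(list(lower = lower, upper = upper, d = length(lower)),
            class = "search_space")
}

#' Heavy-tailed Levy-flight step
#'
#' Draws a d-vector of Levy-distributed steps by Mantegna's algorithm with
#' stability index \code{mu}: \eqn{s = u / |v|^{1/\mu}} with
#' \eqn{u \sim N(0, \sigma_u^2)}, \eqn{v \sim N(0, 1)}, so
#' \eqn{P(|s| > x) \sim x^{-\mu}}. Mantegna's construction is defined for
#' indices below 2; values of \code{mu} at or above 2 (where the stable law
#' degenerates to the Gaussian) are capped at 1.99. Uses the current R RNG
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param d Number of components to draw.
#' @param mu Tail exponent, in (1, 3).
#' @return Numeric vector of length d.
#' @export
levy_step <- function(d, mu = 1.5) {
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 1 || mu >= 3) {
    stop("levy_step: 'mu' must lie in (1, 3)")
  }
  beta <- min(mu, 1.99)
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  stats::rnorm(d, sd = sigma_u) / abs(stats::rnorm(d))^(1 / beta)
}

#' Adaptive discovery-probability schedule
#'
#' Linear decay \eqn{p_a(N_i) = p_{a,max} - (N_i / N_{max})
#' (p_{a,max} - p_{a,min})}: equal to \code{pa_max} at iteration 0 and
#' \code{pa_min} at iteration \code{n_max}.
#'
#' @param iter Current iteration, \code{0 <= iter <= cfg$n_max}.
#' @param cfg A [cuckoo_config()].
#' @return The discovery probability at \code{iter}.
#' @export
adaptive_pa <- function(iter, cfg) {
  check_iter(iter, cfg)
  f <- iter / cfg$n_max
  # convex-combination form: endpoints are exact in floating point
  cfg$pa_max * (1 - f) + cfg$pa_min * f
}

#' Adaptive step-size schedule
#'
#' Geometric decay \eqn{\alpha(N_i) = \alpha_{max} \exp(k N_i)} with
#' \eqn{k = \ln(\alpha_{min}/\alpha_{max}) / N_{max}}: equal to
#' \code{step_max} at iteration 0 and \code{step_min} at iteration
#' \code{n_max}, strictly decreasing in between. With
#' \code{cfg$literal_step_growth} the sign of \eqn{k} is flipped and the
#' step grows instead.
#'
#' @inheritParams adaptive_pa
#' @return The step size at \code{iter}.
#' @export
adaptive_step <- function(iter, cfg) {
  check_iter(iter, cfg)
  k <- if (cfg$literal_step_growth) {
    log(cfg$step_max / cfg$step_min) / cfg$n_max
  } else {
    log(cfg$step_min / cfg$step_max) / cfg$n_max
  }
  cfg$step_max * exp(k * iter)
}

check_iter <- function(iter, cfg) {
  if (!is.numeric(iter) || length(iter) != 1 || iter < 0 || iter > cfg$n_max) {
    stop("iteration must lie in [0, n_max]")
  }
  invisible(iter)
}

#' Levy-flight position proposals
#'
#' Each candidate is \code{clip(position + step * levy * width, bounds)}
#' with an independent Levy draw per coordinate; \code{width} is the per-
#' dimension box width, so the step size is unit-free. Greedy acceptance
#' is done by the optimizer loop, not here.
#'
#' @param positions An n x d matrix of current nest positions.
#' @param step Scalar step size (fraction of box width).
#' @param mu Levy tail exponent.
#' @param space A [search_space()].
#' @return An n x d matrix of candidates, all within bounds.
#' @export
propose_levy_positions <- function(positions, step, mu, space) {
  n <- nrow(positions)
  d <- space$d
  width <- space$upper - space$lower
  steps <- matrix(levy_step(n * d, mu), n, d)
  cand <- positions + step * sweep(steps, 2, width, "*")
  clip_to_box(cand, space)
}

#' Abandon nests at the discovery probability
#'
#' For each nest an independent \eqn{r \sim U(0, 1)} is drawn; if
#' \eqn{r > p_a} the nest is replaced by a uniform random position in the
#' box and re-evaluated (so the abandonment probability is \eqn{1 - p_a}).
#' The incumbent best nest is never abandoned (elitism).
#'
#' @param pop List with \code{positions} (n x d) and \code{fitnesses}
#'   (length n).
#' @param pa Discovery probability in (0, 1].
#' @param space A [search_space()].
#' @param objective Function used to re-evaluate replaced nests.
#' @return The updated population list, with an \code{evals} count of new
#'   objective evaluations.
#' @export
abandon_nests <- function(pop, pa, space, objective) {
  n <- nrow(pop$positions)
  r <- stats::runif(n)
  replace <- r > pa
  replace[which.min(pop$fitnesses)] <- FALSE
  idx <- which(replace)
  for (i in idx) {
    pop$positions[i, ] <- stats::runif(space$d, space$lower, space$upper)
    pop$fitnesses[i] <- objective(pop$positions[i, ])
  }
  pop$evals <- length(idx)
  pop
}

clip_to_box <- function(x, space) {
  x <- pmax(x, matrix(space$lower, nrow(x), space$d, byrow = TRUE))
  pmin(x, matrix(space$upper, nrow(x), space$d, byrow = TRUE))
}

#' Cuckoo search minimization (standard and improved variants)
#'
#' Minimizes \code{objective} over a box. Each iteration: (1) the discovery
#' probability and step size are taken from the adaptive schedules
#' ([adaptive_pa()], [adaptive_step()]) in improved mode, or held fixed in
#' standard mode; (2) every nest emits a Levy-flight proposal which is
#' compared against a randomly chosen nest and replaces it on strict
#' improvement; (3) nests are abandoned per [abandon_nests()]; (4) the best
#' solution so far is updated (elitism), so the best-fitness trace is
#' non-increasing.
#'
#' @param objective Function of a d-vector returning a finite scalar.
#' @param space A [search_space()].
#' @param cfg A [cuckoo_config()].
#' @param seed Optional integer seed (calls [set.seed()]).
#' @return An object of class \code{"optim_result"}: \code{best_position},
#'   \code{best_fitness}, \code{trace} (data frame: iteration, pa, step,
#'   best_fitness), \code{best_positions} (per-iteration best, for model
#'   selection on a validation set), \code{evaluations}, \code{seed},
#'   \code{method}.
#' @export
run_cuckoo <- function(objective, space, cfg = cuckoo_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(space, "search_space"), inherits(cfg, "cuckoo_config"))
  obj <- checked_objective(objective)
  n <- cfg$n_nests
  pop <- list(
    positions = matrix(stats::runif(n * space$d, space$lower, space$upper),
                       n, space$d, byrow = TRUE),
    fitnesses = numeric(n))
  for (i in seq_len(n)) pop$fitnesses[i] <- obj(pop$positions[i, ])
  evals <- n
  best_i <- which.min(pop$fitnesses)
  best_x <- pop$positions[best_i, ]
  best_f <- pop$fitnesses[best_i]

  trace <- vector("list", cfg$n_max)
  best_positions <- matrix(NA_real_, cfg$n_max, space$d)
  improved <- cfg$mode == "improved"
  n_iter <- 0L
  for (it in seq_len(cfg$n_max) - 1L) {
    pa <- if (improved) adaptive_pa(it, cfg) else cfg$fixed_pa
    step <- if (improved) adaptive_step(it, cfg) else cfg$fixed_step
    cand <- propose_levy_positions(pop$positions, step, cfg$levy_mu, space)
    movers <- if (cfg$single_cuckoo) sample.int(n, 1) else seq_len(n)
    for (i in movers) {
      fc <- obj(cand[i, ])
      evals <- evals + 1L
      j <- sample.int(n, 1)
      if (fc < pop$fitnesses[j]) {
        pop$positions[j, ] <- cand[i, ]
        pop$fitnesses[j] <- fc
      }
    }
    pop <- abandon_nests(pop, pa, space, obj)
    evals <- evals + pop$evals
    it_best <- which.min(pop$fitnesses)
    if (pop$fitnesses[it_best] < best_f) {
      best_f <- pop$fitnesses[it_best]
      best_x <- pop$positions[it_best, ]
    }
    n_iter <- n_iter + 1L
    trace[[n_iter]] <- c(iteration = it, pa = pa, step = step,
                         best_fitness = best_f)
    best_positions[n_iter, ] <- best_x
    if (best_f <= cfg$tol) break
  }
  optim_result(best_x, best_f,
               trace = as.data.frame(do.call(rbind, trace[seq_len(n_iter)])),
               best_positions = best_positions[seq_len(n_iter), , drop = FALSE],
               evaluations = evals, seed = seed,
               method = if (improved) "ics" else "cs")
}

#' Global-best particle swarm baseline
#'
#' Textbook PSO with inertia 0.729 and cognitive/social coefficients
#' 1.49445, velocities clamped to half the box width, positions clipped to
#' the box. Runs \code{2 * cfg$n_max} iterations with \code{cfg$n_nests}
#' particles so its evaluation budget matches [run_cuckoo()]'s worst case
#' \code{n_nests * (2 * n_max + 1)}.
#'
#' @inheritParams run_cuckoo
#' @return An \code{"optim_result"}; see [run_cuckoo()].
#' @export
run_pso <- function(objective, space, cfg = cuckoo_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(space, "search_space"))
  obj <- checked_objective(objective)
  n <- cfg$n_nests
  d <- space$d
  n_iter <- 2L * cfg$n_max
  width <- space$upper - space$lower
  vmax <- 0.5 * width
  x <- matrix(stats::runif(n * d, space$lower, space$upper), n, d,
              byrow = TRUE)
  v <- matrix(stats::runif(n * d, -vmax, vmax), n, d, byrow = TRUE)
  f <- apply(x, 1, obj)
  evals <- n
  pbest_x <- x
  pbest_f <- f
  g <- which.min(f)
  best_x <- x[g, ]
  best_f <- f[g]
  trace <- matrix(NA_real_, n_iter, 4)
  best_positions <- matrix(NA_real_, n_iter, d)
  for (it in seq_len(n_iter)) {
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    v <- 0.729 * v + 1.49445 * r1 * (pbest_x - x) +
      1.49445 * r2 * (sweep(-x, 2, best_x, "+"))
    v <- pmax(pmin(v, matrix(vmax, n, d, byrow = TRUE)),
              matrix(-vmax, n, d, byrow = TRUE))
    x <- clip_to_box(x + v, space)
    f <- apply(x, 1, obj)
    evals <- evals + n
    upd <- f < pbest_f
    pbest_x[upd, ] <- x[upd, , drop = FALSE]
    pbest_f[upd] <- f[upd]
    g <- which.min(pbest_f)
    if (pbest_f[g] < best_f) {
      best_f <- pbest_f[g]
      best_x <- pbest_x[g, ]
    }
    trace[it, ] <- c(it - 1, NA, NA, best_f)
    best_positions[it, ] <- best_x
  }
  optim_result(best_x, best_f, trace_df(trace), best_positions,
               evals, seed, "pso")
}

#' Real-coded genetic algorithm baseline
#'
#' Tournament selection (size 2), blend (BLX-0.5) crossover with
#' probability 0.9, Gaussian mutation (sd 10% of box width) with
#' probability 0.1 per gene, one elite individual per generation. Runs
#' \code{2 * cfg$n_max} generations of \code{cfg$n_nests} individuals to
#' match the cuckoo-search evaluation budget.
#'
#' @inheritParams run_cuckoo
#' @return An \code{"optim_result"}; see [run_cuckoo()].
#' @export
run_ga <- function(objective, space, cfg = cuckoo_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(space, "search_space"))
  obj <- checked_objective(objective)
  n <- cfg$n_nests
  d <- space$d
  n_gen <- 2L * cfg$n_max
  width <- space$upper - space$lower
  x <- matrix(stats::runif(n * d, space$lower, space$upper), n, d,
              byrow = TRUE)
  f <- apply(x, 1, obj)
  evals <- n
  best_i <- which.min(f)
  best_x <- x[best_i, ]
  best_f <- f[best_i]
  trace <- matrix(NA_real_, n_gen, 4)
  best_positions <- matrix(NA_real_, n_gen, d)
  for (gen in seq_len(n_gen)) {
    tournament <- function() {
      ij <- sample.int(n, 2)
      if (f[ij[1]] <= f[ij[2]]) ij[1] else ij[2]
    }
    newx <- matrix(0, n, d)
    for (i in seq(1, n, by = 2)) {
      p1 <- x[tournament(), ]
      p2 <- x[tournament(), ]
      if (stats::runif(1) < 0.9) {
        lo <- pmin(p1, p2)
        hi <- pmax(p1, p2)
        span <- hi - lo
        c1 <- stats::runif(d, lo - 0.5 * span, hi + 0.5 * span)
        c2 <- stats::runif(d, lo - 0.5 * span, hi + 0.5 * span)
      } else {
        c1 <- p1
        c2 <- p2
      }
      newx[i, ] <- c1
      if (i + 1 <= n) newx[i + 1, ] <- c2
    }
    mut <- matrix(stats::runif(n * d) < 0.1, n, d)
    noise <- matrix(stats::rnorm(n * d, sd = rep(0.1 * width, each = n)),
                    n, d)
    newx[mut] <- newx[mut] + noise[mut]
    newx <- clip_to_box(newx, space)
    newx[1, ] <- best_x  # elitism
    x <- newx
    f <- apply(x, 1, obj)
    evals <- evals + n
    gi <- which.min(f)
    if (f[gi] < best_f) {
      best_f <- f[gi]
      best_x <- x[gi, ]
    }
    trace[gen, ] <- c(gen - 1, NA, NA, best_f)
    best_positions[gen, ] <- best_x
  }
  optim_result(best_x, best_f, trace_df(trace), best_positions,
               evals, seed, "ga")
}

checked_objective <- function(objective) {
  force(objective)
  function(x) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
      stop("objective returned a non-finite value at (",
           paste(signif(x, 6), collapse = ", "), ")")
    }
    f
  }
}

trace_df <- function(trace) {
  out <- as.data.frame(trace)
  names(out) <- c("iteration", "pa", "step", "best_fitness")
  out
}

optim_result <- function(best_position, best_fitness, trace, best_positions,
                         evaluations, seed, method) {
  structure(
    list(best_position = as.numeric(best_position),
         best_fitness = best_fitness,
         trace = trace,
         best_positions = best_positions,
         evaluations = evaluations,
         seed = seed,
         method = method),
    class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("%s optimization: best fitness %.6g after %d evaluations\n",
              toupper(x$method), x$best_fitness, x$evaluations))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  invisible(x)
}
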