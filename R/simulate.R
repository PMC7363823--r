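#' Kinetic parameters of the synthetic fed-batch fermentation
#'
#' Monod growth with maintenance plus Luedeking-Piret product formation:
#' \deqn{\mu = \mu_{max} S / (K_s + S)}
#' \deqn{dX/dt = \mu X - (F/V) X}
#' \deqn{dS/dt = -\mu X / Y_{xs} - m_s X + F S_{feed}/V - (F/V) S}
#' \deqn{dP/dt = (\alpha_p \mu + \beta_p) X - (F/V) P}
#' \deqn{dV/dt = F}
#' where F is the total liquid feed rate. The default values are
#' conventional fed-batch magnitudes for an amino-acid producer, chosen so
#' the substrate is depleted and product accumulates within a 72-h batch;
#' they are synthetic, not measurements of any real broth.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param K_s Monod half-saturation constant (g/L).
#' @param Y_xs Biomass yield on substrate (g cells / g substrate), in
#'   (0, 1.5].
#' @param m_s Maintenance coefficient (g substrate / g cells / h).
#' @param alpha_p Growth-associated product yield (g product / g cells).
#' @param beta_p Non-growth-associated production rate (1/h).
#' @param S_feed Substrate concentration of the glucose feed (g/L).
#' @return A list of class \code{"kinetic_params"}.
#' @export
kinetic_params <- function(mu_max = 0.12, K_s = 0.3, Y_xs = 0.45,
                           m_s = 0.01, alpha_p = 0.9, beta_p = 0.015,
                           S_feed = 400) {
  vals <- c(mu_max = mu_max, K_s = K_s, Y_xs = Y_xs, m_s = m_s,
            alpha_p = alpha_p, beta_p = beta_p, S_feed = S_feed)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic_params: all parameters must be finite and non-negative")
  }
  if (Y_xs <= 0 || Y_xs > 1.5) stop("kinetic_params: Y_xs must lie in (0, 1.5]")
  structure(as.list(vals), class = "kinetic_params")
}

#' Batch operating schedule
#'
#' Fixed 72-h horizon sampled every 15 min (289 fine-grid points) with
#' offline "lab" samples every 2 h (37 points), mirroring a typical
#' industrial soft-sensor campaign. Feed and setpoint profiles are
#' piecewise-constant in time.
#'
#' @param duration Batch duration in hours.
#' @param dt_fine Auxiliary-input sampling interval (h).
#' @param dt_coarse Offline output sampling interval (h); must be a
#'   multiple of \code{dt_fine}.
#' @param u1_times,u1_values Glucose feed profile (L/h), piecewise constant
#'   from each breakpoint.
#' @param u2_times,u2_values Ammonia feed profile (L/h).
#' @param u3_times,u3_values Air flow profile (L/min).
#' @param r_times,r_values Stirrer speed steps (rpm).
#' @param X0,S0,P0,V0 Initial biomass, substrate, product (g/L) and broth
#'   volume (L).
#' @return A list of class \code{"batch_schedule"}.
#' @export
batch_schedule <- function(duration = 72, dt_fine = 0.25, dt_coarse = 2,
                           u1_times = c(0, 12, 24, 48),
                           u1_values = c(0, 0.25, 0.4, 0.55),
                           u2_times = c(0, 12, 36),
                           u2_values = c(0.01, 0.05, 0.08),
                           u3_times = c(0, 24, 48),
                           u3_values = c(40, 60, 80),
                           r_times = c(0, 24, 48),
                           r_values = c(400, 600, 800),
                           X0 = 0.8, S0 = 25, P0 = 0, V0 = 50) {
  n_fine <- duration / dt_fine
  if (abs(n_fine - round(n_fine)) > 1e-9) {
    stop("batch_schedule: duration must be an integer number of fine steps")
  }
  ratio <- dt_coarse / dt_fine
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("batch_schedule: dt_coarse must be a multiple of dt_fine")
  }
  for (nm in c("u1", "u2", "u3", "r")) {
    tt <- get(paste0(nm, "_times"))
    vv <- get(paste0(nm, "_values"))
    if (length(tt) != length(vv) || is.unsorted(tt) || tt[1] != 0) {
      stop("batch_schedule: ", nm, " profile needs matching times ",
           "(starting at 0, sorted) and values")
    }
  }
  structure(
    list(duration = duration, dt_fine = dt_fine, dt_coarse = dt_coarse,
         u1_times = u1_times, u1_values = u1_values,
         u2_times = u2_times, u2_values = u2_values,
         u3_times = u3_times, u3_values = u3_values,
         r_times = r_times, r_values = r_values,
         X0 = X0, S0 = S0, P0 = P0, V0 = V0),
    class = "batch_schedule")
}

#' Default measurement-noise levels
#'
#' Standard deviations for the seven auxiliary channels (added on the fine
#' grid) and for the three offline concentration assays (added to the 2-h
#' lab samples before spline resampling, mimicking assay error). Set any
#' entry, or everything via \code{scale = 0}, to suppress noise.
#'
#' @param aux Named numeric vector of sds for \code{T_C, pH, r_rpm, DO_pct,
#'   u1, u2, u3}.
#' @param outputs Named numeric vector of sds (g/L) for \code{X_gL, S_gL,
#'   P_gL}.
#' @param scale Common multiplier applied to every sd.
#' @return A list with elements \code{aux} and \code{outputs}.
#' @export
noise_levels <- function(aux = c(T_C = 0.05, pH = 0.01, r_rpm = 1,
                                 DO_pct = 0.5, u1 = 0.002, u2 = 0.001,
                                 u3 = 0.5),
                         outputs = c(X_gL = 0.05, S_gL = 0.08, P_gL = 0.08),
                         scale = 1) {
  list(aux = aux * scale, outputs = outputs * scale)
}

aux_channel_names <- c("T_C", "pH", "r_rpm", "DO_pct", "u1", "u2", "u3")
output_names <- c("X_gL", "S_gL", "P_gL")

step_profile <- function(times, values) {
  if (length(values) == 1) return(function(t) rep(values, length(t)))
  stats::stepfun(times[-1], values, right = FALSE)
}

#' Simulate one fed-batch fermentation batch
#'
#' Integrates the Monod / Luedeking-Piret fed-batch model of
#' [kinetic_params()] with a fixed-step 4th-order Runge-Kutta scheme on the
#' 15-min grid (via \pkg{deSolve}), then builds the measured data exactly as
#' a plant would: seven auxiliary channels are smooth transforms of the
#' state plus sensor noise (dissolved oxygen dips with the oxygen uptake
#' \eqn{\mu X} and with biomass, pH is regulated near 7 with excursions tied
#' to growth and the ammonia feed, temperature is held near 30 C, stirrer
#' speed and feeds follow the schedule), while the three concentrations are
#' subsampled at the 2-h instants, perturbed with assay noise, and
#' spline-interpolated back onto the 15-min grid with
#' [resample_outputs()].
#'
#' @param kin A [kinetic_params()].
#' @param sched A [batch_schedule()].
#' @param noise A [noise_levels()] list.
#' @param seed Optional integer seed for the noise draws.
#' @param batch_id Identifier stored with the batch.
#' @return An object of class \code{"fermentation_batch"}: \code{time}
#'   (289 instants, h), \code{aux} (289 x 7), \code{outputs} (289 x 3,
#'   the spline-resampled measured concentrations, g/L),
#'   \code{true_outputs} (289 x 3 noise-free states), \code{coarse_time},
#'   \code{coarse_outputs} (37 x 3 noisy lab samples), \code{batch_id},
#'   \code{seed}.
#' @export
simulate_batch <- function(kin = kinetic_params(), sched = batch_schedule(),
                           noise = noise_levels(), seed = NULL,
                           batch_id = "batch_01") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(kin, "kinetic_params"), inherits(sched, "batch_schedule"))
  times <- seq(0, sched$duration, by = sched$dt_fine)
  u1 <- step_profile(sched$u1_times, sched$u1_values)
  u2 <- step_profile(sched$u2_times, sched$u2_values)

  derivs <- function(t, state, parms) {
    X <- state[1]; S <- max(state[2], 0); P <- state[3]; V <- state[4]
    F_in <- u1(t) + u2(t)
    mu <- kin$mu_max * S / (kin$K_s + S)
    dX <- mu * X - (F_in / V) * X
    dS <- -mu * X / kin$Y_xs - kin$m_s * X + u1(t) * kin$S_feed / V -
      (F_in / V) * S
    dP <- (kin$alpha_p * mu + kin$beta_p) * X - (F_in / V) * P
    list(c(dX, dS, dP, F_in))
  }
  state0 <- c(X = sched$X0, S = sched$S0, P = sched$P0, V = sched$V0)
  sol <- deSolve::ode(y = state0, times = times, func = derivs,
                      parms = NULL, method = "rk4")
  traj <- as.matrix(sol[, c("X", "S", "P", "V")])
  if (any(!is.finite(traj))) {
    stop("simulate_batch: state blow-up during integration; check mu_max, ",
         "Y_xs and the feed profile")
  }
  if (any(traj[, "V"] <= 0)) {
    stop("simulate_batch: broth volume became non-positive; check the feed ",
         "profile (u1, u2) and V0")
  }
  traj[traj[, "S"] < 0, "S"] <- 0
  true_outputs <- traj[, c("X", "S", "P")]
  colnames(true_outputs) <- output_names

  mu_t <- kin$mu_max * traj[, "S"] / (kin$K_s + traj[, "S"])
  our <- mu_t * traj[, "X"]  # oxygen-uptake proxy
  n <- length(times)
  sd_aux <- noise$aux[aux_channel_names]
  aux <- cbind(
    T_C = 30 + 0.2 * sin(2 * pi * times / 24) +
      stats::rnorm(n, sd = sd_aux["T_C"]),
    pH = 7 - 0.25 * our + 1.2 * u2(times) + stats::rnorm(n, sd = sd_aux["pH"]),
    r_rpm = step_profile(sched$r_times, sched$r_values)(times) +
      stats::rnorm(n, sd = sd_aux["r_rpm"]),
    DO_pct = pmax(100 - 18 * our - 1.0 * traj[, "X"] +
                    stats::rnorm(n, sd = sd_aux["DO_pct"]), 3),
    u1 = u1(times) + stats::rnorm(n, sd = sd_aux["u1"]),
    u2 = u2(times) + stats::rnorm(n, sd = sd_aux["u2"]),
    u3 = step_profile(sched$u3_times, sched$u3_values)(times) +
      stats::rnorm(n, sd = sd_aux["u3"]))

  stride <- round(sched$dt_coarse / sched$dt_fine)
  coarse_idx <- seq(1, n, by = stride)
  coarse_time <- times[coarse_idx]
  sd_out <- noise$outputs[output_names]
  coarse_outputs <- true_outputs[coarse_idx, , drop = FALSE] +
    matrix(stats::rnorm(length(coarse_idx) * 3, sd = rep(sd_out, each =
      length(coarse_idx))), ncol = 3)
  coarse_outputs <- pmax(coarse_outputs, 0)
  colnames(coarse_outputs) <- output_names
  outputs <- pmax(resample_outputs(coarse_outputs, coarse_time, times), 0)
  colnames(outputs) <- output_names

  structure(
    list(time = times, aux = aux, outputs = outputs,
         true_outputs = true_outputs,
         coarse_time = coarse_time, coarse_outputs = coarse_outputs,
         batch_id = batch_id, seed = seed),
    class = "fermentation_batch")
}

#' Spline-resample coarse offline samples onto the fine grid
#'
#' Cubic-spline interpolation (Forsythe--Malcolm--Moler end conditions,
#' \code{stats::spline(method = "fmm")}) per output column, reproducing the
#' usual lab workflow of resampling 2-h assay values onto the 15-min
#' auxiliary grid. The interpolant passes through every coarse knot exactly
#' and reproduces cubic polynomials; no extrapolation is allowed.
#'
#' @param coarse A c x 3 matrix of offline samples.
#' @param coarse_time Length-c vector of sampling instants (h).
#' @param fine_time Target instants; must lie within
#'   \code{range(coarse_time)}.
#' @return A \code{length(fine_time)} x 3 matrix.
#' @export
resample_outputs <- function(coarse, coarse_time, fine_time) {
  coarse <- as.matrix(coarse)
  if (length(coarse_time) != nrow(coarse)) {
    stop("resample_outputs: coarse_time length must match nrow(coarse)")
  }
  if (min(fine_time) < min(coarse_time) - 1e-9 ||
      max(fine_time) > max(coarse_time) + 1e-9) {
    stop("resample_outputs: fine grid extends beyond the coarse span; ",
         "no extrapolation is performed")
  }
  out <- apply(coarse, 2, function(col) {
    stats::spline(coarse_time, col, xout = fine_time, method = "fmm")$y
  })
  matrix(out, nrow = length(fine_time), dimnames = list(NULL, colnames(coarse)))
}

#' Generate a campaign of fermentation batches
#'
#' Draws \code{n_batches} batches whose initial conditions, feed levels and
#' stirrer setpoints are jittered batch-to-batch by a relative spread
#' \code{variation} (uniform in \code{±variation}), emulating a campaign in
#' which initial conditions and feeding strategy are deliberately varied
#' between batches. Per-batch seeds are derived from \code{master_seed}, so
#' the whole campaign is reproducible.
#'
#' @param n_batches Number of batches (default 10).
#' @param variation Relative spread of initial conditions and profiles.
#' @param master_seed Integer seed for the campaign.
#' @param kin,sched,noise Base settings; see [simulate_batch()].
#' @return A list of \code{"fermentation_batch"} objects.
#' @export
generate_campaign <- function(n_batches = 10, variation = 0.05,
                              master_seed = 1, kin = kinetic_params(),
                              sched = batch_schedule(),
                              noise = noise_levels()) {
  if (n_batches < 1) stop("generate_campaign: n_batches must be >= 1")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_batches)
  lapply(seq_len(n_batches), function(i) {
    set.seed(seeds[i])
    jit <- function(v) v * (1 + stats::runif(length(v), -variation, variation))
    sched_i <- sched
    sched_i$X0 <- jit(sched$X0)
    sched_i$S0 <- jit(sched$S0)
    sched_i$V0 <- jit(sched$V0)
    sched_i$u1_values <- jit(sched$u1_values)
    sched_i$u2_values <- jit(sched$u2_values)
    sched_i$u3_values <- jit(sched$u3_values)
    sched_i$r_values <- jit(sched$r_values)
    b <- simulate_batch(kin, sched_i, noise, seed = NULL,
                        batch_id = sprintf("batch_%02d", i))
    b$seed <- seeds[i]
    b
  })
}

#' @export
print.fermentation_batch <- function(x, ...) {
  cat(sprintf("Fermentation batch '%s': %d fine points (%g h), %d lab samples\n",
              x$batch_id, length(x$time), max(x$time), nrow(x$coarse_outputs)))
  cat(sprintf("  final X = %.2f, S = %.2f, P = %.2f g/L\n",
              x$outputs[nrow(x$outputs), 1], x$outputs[nrow(x$outputs), 2],
              x$outputs[nrow(x$outputs), 3]))
  invisible(x)
}

#' Write / read a fermentation batch as CSV
#'
#' The main file holds the fine grid with header \code{time_h, T_C, pH,
#' r_rpm, DO_pct, u1, u2, u3, X_gL, S_gL, P_gL}; the 2-h lab samples are
#' stored in a sibling file \code{<path basename>_coarse.csv} with header
#' \code{time_h, X_gL, S_gL, P_gL}. Numbers are written with full precision
#' and a locale-independent decimal point, and round-trip to below 1e-9.
#'
#' @param batch A \code{"fermentation_batch"}.
#' @param path Path of the main CSV file.
#' @return \code{write_batch_csv} returns \code{path} invisibly;
#'   \code{read_batch_csv} returns a \code{"fermentation_batch"}.
#' @export
write_batch_csv <- function(batch, path) {
  stopifnot(inherits(batch, "fermentation_batch"))
  main <- data.frame(time_h = batch$time, batch$aux, batch$outputs,
                     check.names = FALSE)
  utils::write.csv(format(main, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  coarse <- data.frame(time_h = batch$coarse_time, batch$coarse_outputs,
                       check.names = FALSE)
  utils::write.csv(format(coarse, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   coarse_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

coarse_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_coarse.csv")
}

#' @rdname write_batch_csv
#' @param batch_id Identifier for the read batch; defaults to the file name.
#' @export
read_batch_csv <- function(path, batch_id = NULL) {
  main <- utils::read.csv(path, check.names = FALSE)
  expected <- c("time_h", aux_channel_names, output_names)
  missing <- setdiff(expected, names(main))
  if (length(missing)) {
    stop("read_batch_csv: missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(main[expected])) {
    bad <- which(rowSums(is.na(main[expected])) > 0)[1]
    stop("read_batch_csv: malformed numeric data at line ", bad + 1,
         " of ", path)
  }
  cfile <- coarse_path(path)
  if (!file.exists(cfile)) {
    stop("read_batch_csv: sibling coarse-sample file not found: ", cfile)
  }
  coarse <- utils::read.csv(cfile, check.names = FALSE)
  cexp <- c("time_h", output_names)
  cmiss <- setdiff(cexp, names(coarse))
  if (length(cmiss)) {
    stop("read_batch_csv: missing column(s) in ", cfile, ": ",
         paste(cmiss, collapse = ", "))
  }
  structure(
    list(time = main$time_h,
         aux = as.matrix(main[aux_channel_names]),
         outputs = as.matrix(main[output_names]),
         true_outputs = NULL,
         coarse_time = coarse$time_h,
         coarse_outputs = as.matrix(coarse[output_names]),
         batch_id = batch_id %||% sub("\\.csv$", "", basename(path)),
         seed = NA_integer_),
    class = "fermentation_batch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
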