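test_that("a default batch has the campaign sampling structure", {
  b <- simulate_batch(seed = 51)
  expect_equal(length(b$time), 289)          # 72 h at 15-min steps
  expect_equal(dim(b$aux), c(289, 7))
  expect_equal(dim(b$outputs), c(289, 3))
  expect_equal(dim(b$coarse_outputs), c(37, 3))  # 2-h lab samples
  expect_equal(colnames(b$aux),
               c("T_C", "pH", "r_rpm", "DO_pct", "u1", "u2", "u3"))
  expect_true(all(b$outputs >= 0))
  expect_true(all(b$coarse_time %in% b$time))
})

test_that("frozen dynamics give constant trajectories", {
  kin <- kinetic_params(mu_max = 0, m_s = 0, beta_p = 0)
  sch <- batch_schedule(u1_times = 0, u1_values = 0,
                        u2_times = 0, u2_values = 0)
  b <- simulate_batch(kin, sch, noise_levels(scale = 0))
  expect_equal(max(abs(sweep(b$true_outputs, 2, b$true_outputs[1, ]))), 0)
})

test_that("batches are bitwise reproducible per seed", {
  expect_identical(simulate_batch(seed = 52), simulate_batch(seed = 52))
  c1 <- generate_campaign(3, master_seed = 53)
  c2 <- generate_campaign(3, master_seed = 53)
  expect_identical(c1, c2)
})

test_that("no variation and no noise give identical batches", {
  camp <- generate_campaign(3, variation = 0, master_seed = 54,
                            noise = noise_levels(scale = 0))
  for (field in c("aux", "outputs", "coarse_outputs")) {
    expect_equal(camp[[1]][[field]], camp[[2]][[field]])
    expect_equal(camp[[1]][[field]], camp[[3]][[field]])
  }
  expect_equal(length(unique(vapply(camp, function(b) b$batch_id, ""))), 3)
})

test_that("the default campaign has 10 distinct varied batches", {
  camp <- generate_campaign(master_seed = 55)
  expect_length(camp, 10)
  ids <- vapply(camp, function(b) b$batch_id, "")
  expect_equal(length(unique(ids)), 10)
  finals <- vapply(camp, function(b) b$outputs[289, 1], numeric(1))
  expect_gt(stats::sd(finals), 0)  # initial-condition/feed variation shows
})

test_that("substrate-to-biomass balance closes without maintenance", {
  kin <- kinetic_params(m_s = 0, beta_p = 0)
  sch <- batch_schedule(u1_times = 0, u1_values = 0,
                        u2_times = 0, u2_values = 0)
  b <- simulate_batch(kin, sch, noise_levels(scale = 0))
  dX <- b$true_outputs[289, 1] - b$true_outputs[1, 1]
  dS <- b$true_outputs[1, 2] - b$true_outputs[289, 2]
  expect_equal(unname(dX) / kin$Y_xs, unname(dS), tolerance = 0.01)
})

test_that("no-feed batches deplete substrate and accumulate product", {
  sch <- batch_schedule(u1_times = 0, u1_values = 0,
                        u2_times = 0, u2_values = 0)
  b <- simulate_batch(sched = sch, noise = noise_levels(scale = 0))
  expect_true(all(diff(b$true_outputs[, 2]) <= 1e-9))
  expect_true(all(diff(b$true_outputs[, 3]) >= -1e-9))
})

test_that("state increments carry the expected correlation structure", {
  b <- simulate_batch(noise = noise_levels(scale = 0), seed = 56)
  d <- diff(b$true_outputs)
  expect_lt(stats::cor(d[, 2], d[, 1]), 0)  # substrate consumed as cells grow
  expect_gt(stats::cor(d[, 1], d[, 3]), 0)  # product tracks growth
})

test_that("spline resampling is exact at knots, for lines and for cubics", {
  ct <- seq(0, 72, by = 2)
  fine <- seq(0, 72, by = 0.25)
  # linear data stay linear
  lin <- cbind(2 + 0.5 * ct, 1 - 0.1 * ct, ct)
  r <- resample_outputs(lin, ct, fine)
  expect_equal(r[, 1], 2 + 0.5 * fine, tolerance = 1e-10)
  # knots are interpolated exactly
  set.seed(57)
  rough <- matrix(runif(37 * 3), 37, 3)
  rr <- resample_outputs(rough, ct, fine)
  expect_equal(rr[fine %in% ct, ], rough, tolerance = 1e-12,
               ignore_attr = TRUE)
  # cubic polynomials are reproduced
  f <- function(t) 1e-3 * t^3 - 0.05 * t^2 + t + 2
  rc <- resample_outputs(cbind(f(ct), f(ct), f(ct)), ct, fine)
  expect_lt(max(abs(rc[, 1] - f(fine))), 1e-8)
  # no extrapolation
  expect_error(resample_outputs(lin, ct, seq(-1, 10)), "extrapolation")
})

test_that("state blow-up and volume loss are reported", {
  # a net outflow drains the broth: volume must be flagged, not NaN-ed
  expect_error(
    simulate_batch(sched = batch_schedule(V0 = 10, u1_times = 0,
                                          u1_values = -2,
                                          u2_times = 0, u2_values = 0)),
    "blow-up|volume")
})

test_that("batch CSV round-trips and validates its schema", {
  b <- simulate_batch(seed = 58)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "b1.csv")
  write_batch_csv(b, path)
  expect_true(file.exists(file.path(dir, "b1_coarse.csv")))
  b2 <- read_batch_csv(path)
  expect_lt(max(abs(b2$aux - b$aux)), 1e-9)
  expect_lt(max(abs(b2$outputs - b$outputs)), 1e-9)
  expect_lt(max(abs(b2$coarse_outputs - b$coarse_outputs)), 1e-9)
  expect_equal(b2$time, b$time, tolerance = 1e-9)
  # missing column is named
  broken <- utils::read.csv(path, check.names = FALSE)
  broken$DO_pct <- NULL
  utils::write.csv(broken, path, row.names = FALSE)
  expect_error(read_batch_csv(path), "DO_pct")
})
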