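test_that("levy_step is deterministic given a seed and heavy-tailed", {
  set.seed(1); a <- levy_step(100, 1.5)
  set.seed(1); b <- levy_step(100, 1.5)
  expect_identical(a, b)
  expect_error(levy_step(10, 3.5), "1, 3")
  expect_error(levy_step(10, 1), "1, 3")
  # Hill tail-index estimate of |steps| near the stability index 1.5
  set.seed(2)
  s <- sort(abs(levy_step(1e5, 1.5)), decreasing = TRUE)
  k <- 5000
  hill <- 1 / (mean(log(s[1:k])) - log(s[k + 1]))
  expect_gt(hill, 1.2)
  expect_lt(hill, 1.8)
})

test_that("discovery-probability schedule is exactly linear", {
  cfg <- cuckoo_config(n_max = 100, pa_max = 0.5, pa_min = 0.01)
  expect_identical(adaptive_pa(0, cfg), 0.5)
  expect_identical(adaptive_pa(100, cfg), 0.01)
  expect_equal(adaptive_pa(50, cfg), 0.255, tolerance = 1e-15)
  iters <- 0:100
  pas <- sapply(iters, adaptive_pa, cfg = cfg)
  expect_equal(diff(pas), rep(-(0.5 - 0.01) / 100, 100), tolerance = 1e-12)
  expect_error(adaptive_pa(101, cfg), "0, n_max")
  expect_error(adaptive_pa(-1, cfg), "0, n_max")
})

test_that("step-size schedule is exactly geometric with matched endpoints", {
  cfg <- cuckoo_config(n_max = 100, step_max = 0.5, step_min = 0.01)
  expect_equal(adaptive_step(0, cfg), 0.5, tolerance = 1e-12)
  expect_equal(adaptive_step(100, cfg), 0.01, tolerance = 1e-12)
  expect_equal(adaptive_step(50, cfg), sqrt(0.5 * 0.01), tolerance = 1e-12)
  steps <- sapply(0:100, adaptive_step, cfg = cfg)
  expect_true(all(diff(steps) < 0))
  ratios <- steps[-1] / steps[-101]
  expect_equal(ratios, rep(ratios[1], 100), tolerance = 1e-10)
  # literal growth flag reproduces the increasing variant
  cfgl <- cuckoo_config(n_max = 100, step_max = 0.5, step_min = 0.01,
                        literal_step_growth = TRUE)
  expect_equal(adaptive_step(0, cfgl), 0.5, tolerance = 1e-12)
  expect_gt(adaptive_step(100, cfgl), adaptive_step(0, cfgl))
})

test_that("standard mode gives a constant schedule", {
  cfg <- cuckoo_config(mode = "standard", fixed_pa = 0.25, fixed_step = 0.3,
                       n_nests = 5, n_max = 10)
  res <- run_cuckoo(sphere, sphere_space(2), cfg, seed = 4)
  expect_true(all(res$trace$pa == 0.25))
  expect_true(all(res$trace$step == 0.3))
})

test_that("levy proposals respect bounds, zero step, and seeding", {
  space <- search_space(c(-1, 0), c(1, 2))
  pos <- matrix(c(0, 1, 0.5, 0.5, -0.9, 1.9), 3, 2, byrow = TRUE)
  expect_equal(propose_levy_positions(pos, 0, 1.5, space), pos)
  set.seed(5); a <- propose_levy_positions(pos, 0.4, 1.5, space)
  set.seed(5); b <- propose_levy_positions(pos, 0.4, 1.5, space)
  expect_identical(a, b)
  expect_true(all(a >= -1e-12 + matrix(space$lower, 3, 2, byrow = TRUE)))
  expect_true(all(a <= 1e-12 + matrix(space$upper, 3, 2, byrow = TRUE)))
})

test_that("abandonment spares the best nest and hits the expected rate", {
  space <- search_space(c(0, 0), c(1, 1))
  pop <- list(positions = matrix(runif(40), 20, 2),
              fitnesses = runif(20))
  # pa = 1: r > 1 impossible, population unchanged
  out <- abandon_nests(pop, 1, space, sphere)
  expect_identical(out$positions, pop$positions)
  expect_equal(out$evals, 0)
  # pa -> 0: every non-best nest resampled within bounds
  set.seed(6)
  out0 <- abandon_nests(pop, 1e-12, space, sphere)
  expect_equal(out0$evals, 19)
  best <- which.min(pop$fitnesses)
  expect_identical(out0$positions[best, ], pop$positions[best, ])
  expect_true(all(out0$positions >= 0 & out0$positions <= 1))
  # expected abandoned fraction at pa = 0.3 is 0.7 (excluding the elite)
  set.seed(7)
  n_trials <- 500
  frac <- replicate(n_trials, {
    abandon_nests(pop, 0.3, space, sphere)$evals / 19
  })
  expect_equal(mean(frac), 0.7, tolerance = 0.02)
})

test_that("cuckoo search handles a constant objective and traces elitism", {
  cfg <- micro_cfg()
  res <- run_cuckoo(function(x) 42, sphere_space(2), cfg, seed = 8)
  expect_equal(res$best_fitness, 42)
  expect_true(all(res$trace$best_fitness == 42))
})

test_that("best-so-far trace is monotone and points stay in the box", {
  for (s in 1:3) {
    for (runner in list(run_cuckoo, run_pso, run_ga)) {
      res <- runner(sphere, sphere_space(3),
                    cuckoo_config(n_nests = 8, n_max = 12), seed = s)
      expect_true(all(diff(res$trace$best_fitness) <= 0))
      expect_true(all(res$best_position >= -5 & res$best_position <= 5))
    }
  }
})

test_that("optimizers are reproducible and respect the evaluation budget", {
  cfg <- cuckoo_config(n_nests = 7, n_max = 9)
  for (runner in list(run_cuckoo, run_pso, run_ga)) {
    a <- runner(sphere, sphere_space(2), cfg, seed = 12)
    b <- runner(sphere, sphere_space(2), cfg, seed = 12)
    expect_identical(a, b)
    expect_lte(a$evaluations, 7 * (2 * 9 + 1))
  }
})

test_that("optimizers find the sphere minimum at a modest budget", {
  res <- sapply(1:5, function(s) {
    run_cuckoo(sphere, sphere_space(3),
               cuckoo_config(n_nests = 24, n_max = 60), seed = s)$best_fitness
  })
  expect_gte(sum(res <= 1e-1), 4)
  pso <- sapply(1:5, function(s) {
    run_pso(sphere, sphere_space(3), cuckoo_config(n_nests = 12, n_max = 30),
            seed = s)$best_fitness
  })
  expect_gte(sum(pso <= 1e-1), 4)
  ga <- sapply(1:5, function(s) {
    run_ga(sphere, sphere_space(3), cuckoo_config(n_nests = 12, n_max = 30),
           seed = s)$best_fitness
  })
  expect_gte(sum(ga <= 1e-1), 4)
})

test_that("non-finite objectives are reported with the offending point", {
  expect_error(
    run_cuckoo(function(x) NaN, sphere_space(2), micro_cfg(), seed = 1),
    "non-finite")
})

test_that("config validation enforces the documented invariants", {
  expect_error(cuckoo_config(pa_min = 0.6, pa_max = 0.5), "pa_min")
  expect_error(cuckoo_config(step_min = 0.6, step_max = 0.5), "step_min")
  expect_error(cuckoo_config(levy_mu = 3), "levy_mu")
  expect_error(cuckoo_config(n_nests = 1), "n_nests")
  expect_error(search_space(c(0, 1), c(1, 1)), "lower < upper")
})
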