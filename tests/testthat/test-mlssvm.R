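test_that("assembled system has the documented block structure", {
  set.seed(31)
  d <- random_training_set(4, 2, 3)
  sys <- assemble_mlssvm_system(d$x, d$y, gamma = 5, lambda = 2, sigma = 0.8)
  expect_equal(dim(sys$H), c(12, 12))
  expect_equal(dim(sys$P), c(12, 3))
  expect_equal(colSums(sys$P), c(4, 4, 4))
  expect_true(all(rowSums(sys$P) == 1))
  expect_identical(sys$H, t(sys$H))
  # every l x l block of Omega equals K; off-diagonal blocks of Q are zero:
  # off-diagonal blocks of H must equal K exactly
  K <- sys$K
  expect_equal(sys$H[1:4, 5:8], K, tolerance = 1e-14)
  expect_equal(sys$H[9:12, 1:4], K, tolerance = 1e-14)
  # diagonal blocks: K + (m/lambda) K + I/gamma
  expect_equal(sys$H[1:4, 1:4], K + (3 / 2) * K + diag(4) / 5,
               tolerance = 1e-14)
  # output-major stacking
  expect_equal(sys$y_stacked, as.vector(d$y))
})

test_that("single-output system reduces to (1 + 1/lambda) K + I/gamma", {
  d <- random_training_set(5, 2, 1, seed = 32)
  sys <- assemble_mlssvm_system(d$x, d$y, gamma = 4, lambda = 3, sigma = 1)
  expect_equal(sys$H, (1 + 1 / 3) * sys$K + diag(5) / 4, tolerance = 1e-14)
})

test_that("zero targets give the zero solution", {
  d <- random_training_set(6, 2, 2, seed = 33)
  fit <- mlssvm(d$x, matrix(0, 6, 2), gamma = 10, lambda = 1, sigma = 1)
  expect_equal(fit$dual_coeffs, matrix(0, 6, 2), tolerance = 1e-12)
  expect_equal(fit$bias, c(0, 0), tolerance = 1e-12)
})

test_that("reduced and full solvers match the direct dense KKT solve", {
  set.seed(34)
  for (rep in 1:10) {
    l <- sample(3:20, 1); n <- sample(1:4, 1); m <- sample(1:3, 1)
    d <- random_training_set(l, n, m)
    g <- 2^runif(1, -3, 6); lam <- 2^runif(1, -4, 4)
    sig <- 2^runif(1, -2, 2)
    oracle <- direct_kkt_solve(d$x, d$y, g, lam, sig)
    red <- mlssvm(d$x, d$y, g, lam, sig, method = "reduced")
    ful <- mlssvm(d$x, d$y, g, lam, sig, method = "full")
    expect_equal(red$dual_coeffs, oracle$dual_coeffs, tolerance = 1e-8)
    expect_equal(red$bias, oracle$bias, tolerance = 1e-8)
    expect_equal(ful$dual_coeffs, oracle$dual_coeffs, tolerance = 1e-8)
    # returned solution satisfies the original system
    sys <- assemble_mlssvm_system(d$x, d$y, g, lam, sig)
    a <- as.vector(red$dual_coeffs)
    expect_lt(max(abs(crossprod(sys$P, a))), 1e-8)
    resid <- sys$P %*% red$bias + sys$H %*% a - sys$y_stacked
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("KKT identities hold on every fitted model", {
  set.seed(35)
  for (rep in 1:5) {
    d <- random_training_set(sample(5:15, 1), 2, sample(1:3, 1))
    g <- 2^runif(1, 0, 8)
    fit <- mlssvm(d$x, d$y, g, 2^runif(1, -3, 3), 2^runif(1, -1, 1))
    expect_lt(max(abs(colSums(fit$dual_coeffs))), 1e-8)
    expect_equal(d$y - predict(fit, d$x), fit$dual_coeffs / g,
                 tolerance = 1e-7)
    expect_equal(residuals(fit), fit$dual_coeffs / g)
  }
})

test_that("two identical output columns yield identical coefficients", {
  d <- random_training_set(8, 2, 1, seed = 36)
  y2 <- cbind(d$y, d$y)
  fit <- mlssvm(d$x, y2, gamma = 20, lambda = 2, sigma = 0.7)
  expect_equal(fit$dual_coeffs[, 1], fit$dual_coeffs[, 2], tolerance = 1e-10)
  expect_equal(fit$bias[1], fit$bias[2], tolerance = 1e-10)
})

test_that("prediction matches the triple-loop kernel expansion", {
  set.seed(37)
  d <- random_training_set(7, 2, 3)
  lam <- 1.7
  fit <- mlssvm(d$x, d$y, gamma = 15, lambda = lam, sigma = 0.5)
  q <- matrix(runif(10), 5, 2)
  got <- predict(fit, q)
  A <- fit$dual_coeffs
  m <- 3
  want <- matrix(0, 5, m)
  for (t in 1:m) for (r in 1:5) {
    acc <- 0
    for (j in 1:7) {
      k <- rbf_kernel(q[r, ], d$x[j, ], 0.5)
      acc <- acc + sum(A[j, ]) * k + (m / lam) * A[j, t] * k
    }
    want[r, t] <- acc + fit$bias[t]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("MLSSVM reduces to LSSVM for m = 1 and large lambda", {
  set.seed(38)
  d <- random_training_set(15, 2, 1)
  multi <- mlssvm(d$x, d$y, gamma = 50, lambda = 1e10, sigma = 0.7)
  single <- lssvm(d$x, d$y[, 1], g = 50, sigma = 0.7)
  q <- matrix(runif(40), 20, 2)
  expect_lt(max(abs(predict(multi, q)[, 1] - predict(single, q))), 1e-6)
})

test_that("permuting training rows permutes A and leaves predictions fixed", {
  set.seed(39)
  d <- random_training_set(9, 3, 2)
  fit <- mlssvm(d$x, d$y, gamma = 10, lambda = 1, sigma = 0.8)
  p <- sample(9)
  fitp <- mlssvm(d$x[p, ], d$y[p, , drop = FALSE],
                 gamma = 10, lambda = 1, sigma = 0.8)
  expect_equal(fitp$dual_coeffs, fit$dual_coeffs[p, ], tolerance = 1e-10)
  q <- matrix(runif(8), 4, 2)
  # same model function regardless of row order
  expect_equal(predict(fitp, cbind(q, q[, 1])[, 1:3]),
               predict(fit, cbind(q, q[, 1])[, 1:3]), tolerance = 1e-10)
})

test_that("compensated refinement polishes ill-conditioned solutions", {
  set.seed(40)
  d <- random_training_set(12, 2, 2)
  g <- 2^14; lam <- 2^-8; sig <- 2
  plain <- mlssvm(d$x, d$y, g, lam, sig)
  polished <- mlssvm(d$x, d$y, g, lam, sig, refine = 3)
  oracle <- direct_kkt_solve(d$x, d$y, g, lam, sig, refine = 3)
  expect_equal(polished$dual_coeffs, oracle$dual_coeffs, tolerance = 1e-9)
  # the polished solution still satisfies the KKT system tightly
  sys <- assemble_mlssvm_system(d$x, d$y, g, lam, sig)
  resid <- max(abs(sys$P %*% polished$bias +
                     sys$H %*% as.vector(polished$dual_coeffs) -
                     sys$y_stacked))
  expect_lt(resid, 1e-8)
  expect_lt(max(abs(plain$dual_coeffs - polished$dual_coeffs)), 1e-3)
})

test_that("hyperparameter and shape validation errors are informative", {
  d <- random_training_set(5, 2, 2, seed = 41)
  expect_error(mlssvm(d$x, d$y, gamma = -1), "positive")
  expect_error(mlssvm(d$x, d$y, lambda = 0), "positive")
  expect_error(mlssvm(d$x, d$y[1:4, ]), "row counts")
  fit <- mlssvm(d$x, d$y)
  expect_error(predict(fit, matrix(1, 2, 5)), "columns")
})
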