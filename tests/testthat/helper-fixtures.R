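# Shared fixtures and independent oracles for the test suite.

random_training_set <- function(l, n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(x = matrix(stats::runif(l * n), l, n),
       y = matrix(stats::rnorm(l * m), l, m))
}

# Independent oracle: dense LU solve of the full (ml + m) saddle-point
# KKT system, optionally polished by compensated-residual refinement.
direct_kkt_solve <- function(x, y, gamma, lambda, sigma, refine = 0L) {
  sys <- assemble_mlssvm_system(x, y, gamma, lambda, sigma)
  m <- sys$m
  M <- rbind(cbind(matrix(0, m, m), t(sys$P)), cbind(sys$P, sys$H))
  rhs <- c(rep(0, m), sys$y_stacked)
  sol <- solve(M, rhs)
  for (s in seq_len(refine)) {
    sol <- sol + solve(M, rhs - fermsensor:::comp_matvec(M, sol))
  }
  list(bias = sol[seq_len(m)],
       dual_coeffs = matrix(sol[-seq_len(m)], sys$l, sys$m))
}

# cheap campaign for pipeline tests: full 72-h structure, light noise
tiny_campaign <- function(n_batches = 4, master_seed = 11, noise_scale = 1) {
  generate_campaign(n_batches, variation = 0.05, master_seed = master_seed,
                    noise = noise_levels(scale = noise_scale))
}

micro_cfg <- function(...) cuckoo_config(n_nests = 6, n_max = 5, ...)

sphere <- function(x) sum(x^2)
sphere_space <- function(d = 3) search_space(rep(-5, d), rep(5, d))
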