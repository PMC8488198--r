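# Shared fixture builders and independent oracles. Oracles are written from
# the model's densities directly (dense multivariate-normal arithmetic with
# explicit solves), independent of the package's constant-dropped kernels.

# Shrunk AR-1 correlation matrix.
ar1_corr <- function(m, rho, shrink = 0.1) {
  (1 - shrink) * rho^abs(outer(seq_len(m), seq_len(m), "-")) +
    shrink * diag(m)
}

rand_summary_data <- function(m, rho1 = 0.5, rho2 = 0.3, z_sd = 1.5,
                              shrink = 0.1, identity_ld = FALSE) {
  if (identity_ld) {
    R1 <- diag(m)
    R2 <- diag(m)
  } else {
    R1 <- ar1_corr(m, rho1, shrink)
    R2 <- ar1_corr(m, rho2, shrink)
  }
  GeneSummaryData("g", rnorm(m, 0, z_sd), rnorm(m, 0, z_sd), R1, R2)
}

# Dense log N(x; mu, S) with explicit Cholesky solves.
ldmvn <- function(x, mu, S) {
  ch <- chol(S)
  -0.5 * sum(backsolve(ch, x - mu, transpose = TRUE)^2) -
    sum(log(diag(ch))) - length(x) / 2 * log(2 * pi)
}

# Full complete-data log joint density (all constants retained): sum of the
# eQTL arm, GWAS arm and prior densities.
dense_joint_loglik <- function(data, gamma, params) {
  m <- length(gamma)
  R1 <- ldEqtl(data)
  R2 <- ldGwas(data)
  ldmvn(eqtlZ(data), params@tau * as.vector(R1 %*% gamma), R1) +
    ldmvn(gwasZ(data), params@alpha_prime * as.vector(R2 %*% gamma), R2) +
    ldmvn(gamma, rep(0, m), params@sigma2_gamma * diag(m))
}

# The parameter-free constant the package drops, recomputed independently:
# the two zero-mean densities evaluated at the observed z-scores.
dense_dropped_constant <- function(data) {
  m <- nSnps(data)
  ldmvn(eqtlZ(data), rep(0, m), ldEqtl(data)) +
    ldmvn(gwasZ(data), rep(0, m), ldGwas(data))
}

# Numerical maximizer of the exact marginal likelihood over
# (log sigma2_gamma, alpha_prime) in the reduced model.
numerical_mle <- function(data, null_model = FALSE) {
  nll <- function(th) {
    a <- if (null_model) 0 else th[2L]
    -exactMarginalLoglik(data, ModelParams(exp(th[1L]), a, 1,
                                           null_model = null_model))
  }
  start <- if (null_model) log(0.1) else c(log(0.1), 0)
  op <- optim(start, nll,
              method = if (null_model) "Brent" else "Nelder-Mead",
              lower = if (null_model) -20 else -Inf,
              upper = if (null_model) 10 else Inf,
              control = list(reltol = 1e-14, maxit = 10000))
  list(sigma2 = exp(op$par[1L]),
       alpha_prime = if (null_model) 0 else op$par[2L],
       loglik = -op$value)
}
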