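test_that("ELBO matches a termwise hand evaluation and the marginal bound", {
  # m = 1, R = [1], z = 0, alpha' = 0, tau = 1, sigma2 = 1, q = N(0, 0.5):
  # -s2/2 - (mu^2+s2)/2 - log(2 pi)/2 + log(2 pi e s2)/2
  d <- GeneSummaryData("g", 0, 0, diag(1), diag(1))
  q <- VariationalPosterior(0, 0.5)
  hand <- -0.25 - 0.25 - 0.5 * log(2 * pi) + 0.5 * log(2 * pi * exp(1) * 0.5)
  expect_equal(elbo(d, ModelParams(sigma2_gamma = 1), q), hand)

  # the ELBO never exceeds the (constant-dropped) exact marginal
  set.seed(11)
  for (i in 1:10) {
    m <- sample(1:6, 1)
    dd <- rand_summary_data(m)
    p <- ModelParams(sigma2_gamma = runif(1, 0.05, 2), alpha_prime = rnorm(1),
                     tau = runif(1, 0.5, 1.5))
    qq <- VariationalPosterior(rnorm(m), runif(m, 0.1, 1))
    expect_lte(elbo(dd, p, qq),
               exactMarginalLoglik(dd, p, drop_constant = TRUE) + 1e-9)
  }
})

test_that("posterior sweep reproduces the exact coordinate conditionals", {
  # identity LD, tau = 1: the fixed point is available in closed form
  set.seed(21)
  m <- 4L
  d <- rand_summary_data(m, identity_ld = TRUE)
  p <- ModelParams(sigma2_gamma = 0.7, alpha_prime = 0.6, tau = 1)
  q <- VariationalPosterior(rep(0, m), rep(1, m))
  for (i in 1:50) q <- updatePosterior(d, p, q)
  expect_equal(posteriorMean(q),
               (eqtlZ(d) + 0.6 * gwasZ(d)) / (1 + 0.36 + 1 / 0.7),
               tolerance = 1e-10)

  # one coordinate update equals the exact full conditional of gamma_k given
  # the others: maximize the kernel numerically in that coordinate and
  # measure its curvature
  dc <- rand_summary_data(5)
  pc <- ModelParams(sigma2_gamma = 0.5, alpha_prime = 0.8, tau = 1.2)
  mu0 <- rnorm(5)
  upd <- updatePosterior(dc, pc, VariationalPosterior(mu0, rep(0.5, 5)))
  # coordinate 1 is updated first, with the others still at mu0
  kernel_k <- function(g1) {
    loglikKernel(dc, c(g1, mu0[-1L]), pc)
  }
  op <- optimize(kernel_k, c(-20, 20), maximum = TRUE, tol = 1e-12)
  h <- 1e-4
  curv <- (kernel_k(op$maximum + h) - 2 * kernel_k(op$maximum) +
             kernel_k(op$maximum - h)) / h^2
  expect_equal(posteriorMean(upd)[1L], op$maximum, tolerance = 1e-6)
  expect_equal(posteriorVar(upd)[1L], -1 / curv, tolerance = 1e-4)

  # alpha' = 0: the sweep cannot depend on any GWAS quantity
  p0 <- ModelParams(sigma2_gamma = 0.5, alpha_prime = 0, tau = 1.2)
  dA <- GeneSummaryData("g", eqtlZ(dc), gwasZ(dc), ldEqtl(dc), ldGwas(dc))
  dB <- GeneSummaryData("g", eqtlZ(dc), rev(gwasZ(dc)), ldEqtl(dc), diag(5))
  qA <- updatePosterior(dA, p0, VariationalPosterior(mu0, rep(1, 5)))
  qB <- updatePosterior(dB, p0, VariationalPosterior(mu0, rep(1, 5)))
  expect_identical(posteriorMean(qA), posteriorMean(qB))
})

test_that("parameter update maximizes the ELBO and respects the null", {
  set.seed(31)
  m <- 5L
  d <- rand_summary_data(m)
  # mean-zero posterior: sigma2 collapses onto the shared variance
  q0 <- VariationalPosterior(rep(0, m), rep(0.3, m))
  p <- updateParameters(d, ModelParams(), q0)
  expect_equal(p@sigma2_gamma, 0.3)

  # each returned parameter is a local maximizer of the ELBO
  q <- VariationalPosterior(rnorm(m), runif(m, 0.2, 0.8))
  p <- updateParameters(d, ModelParams(sigma2_gamma = 0.4, alpha_prime = 0.2),
                        q)
  base <- elbo(d, p, q)
  for (eps in c(-1e-3, 1e-3)) {
    expect_lt(elbo(d, ModelParams(p@sigma2_gamma + eps, p@alpha_prime, p@tau),
                   q), base)
    expect_lt(elbo(d, ModelParams(p@sigma2_gamma, p@alpha_prime + eps, p@tau),
                   q), base)
    expect_lt(elbo(d, ModelParams(p@sigma2_gamma, p@alpha_prime, p@tau + eps),
                   q), base)
  }

  # the null constraint pins alpha' at exactly zero
  pn <- updateParameters(d, ModelParams(null_model = TRUE), q)
  expect_identical(pn@alpha_prime, 0)
  expect_true(pn@null_model)
})

test_that("expansion reduction preserves the marginal likelihood", {
  p <- ModelParams(sigma2_gamma = 0.25, alpha_prime = 1, tau = 2)
  r <- reduceExpansion(p)
  expect_equal(r@sigma2_gamma, 1)
  expect_equal(r@alpha_prime, 0.5)
  expect_equal(r@tau, 1)
  expect_equal(reduceExpansion(ModelParams(0.3, 0.4, 1))@sigma2_gamma, 0.3)

  set.seed(41)
  for (i in 1:5) {
    d <- rand_summary_data(sample(1:4, 1))
    p <- ModelParams(runif(1, 0.1, 2), rnorm(1), runif(1, 0.3, 3))
    expect_equal(exactMarginalLoglik(d, p),
                 exactMarginalLoglik(d, reduceExpansion(p)),
                 tolerance = 1e-9)
  }
  expect_warning(r0 <- reduceExpansion(ModelParams(1, 0.5, 0)), "degenerate")
  expect_equal(r0@sigma2_gamma, 1e-8)
})

test_that("fit recovers the marginal-likelihood maximizer", {
  # m = 1: compare against a grid search over sigma2
  set.seed(51)
  d1 <- GeneSummaryData("g", 2.5, 0, diag(1), diag(1))
  fit <- fitCommS4(d1, null_model = TRUE, tol = 1e-10)
  grid <- exp(seq(log(1e-6), log(100), length.out = 20000))
  ll <- vapply(grid, function(s) {
    exactMarginalLoglik(d1, ModelParams(s, 0, 1, null_model = TRUE))
  }, numeric(1))
  expect_equal(fitParams(fit)@sigma2_gamma, grid[which.max(ll)],
               tolerance = 1e-3)
  # m = 1: ELBO at the optimum equals the exact marginal (mean field exact)
  expect_equal(elboFinal(fit),
               exactMarginalLoglik(d1, fitParams(fit), drop_constant = TRUE),
               tolerance = 1e-8)

  # m <= 5: joint numerical maximization oracle
  for (m in c(2L, 5L)) {
    d <- rand_summary_data(m, identity_ld = TRUE)
    fit <- fitCommS4(d, tol = 1e-10)
    mle <- numerical_mle(d)
    expect_equal(fitParams(fit)@sigma2_gamma, mle$sigma2, tolerance = 1e-2)
    expect_equal(fitParams(fit)@alpha_prime, mle$alpha_prime,
                 tolerance = 1e-2)
  }

  # no signal: the coefficient is zero and the prior variance hits its floor
  dz <- GeneSummaryData("g", rep(0, 3), rep(0, 3), diag(3), diag(3))
  fz <- fitCommS4(dz)
  expect_equal(fitParams(fz)@alpha_prime, 0)
  expect_equal(fitParams(fz)@sigma2_gamma, 1e-8)
})

test_that("fit is deterministic and its trace is monotone, with and without PX", {
  set.seed(61)
  d <- rand_summary_data(30, rho1 = 0.8, rho2 = 0.8, shrink = 0.05)
  f1 <- fitCommS4(d)
  f2 <- fitCommS4(d)
  expect_identical(elboTrace(f1), elboTrace(f2))
  expect_identical(posteriorMean(f1), posteriorMean(f2))
  for (px in c(TRUE, FALSE)) {
    f <- fitCommS4(d, use_px = px)
    expect_gte(min(diff(elboTrace(f))), -1e-8)
  }
  # PX does not end lower, and converges in no more iterations here
  f_px <- fitCommS4(d, use_px = TRUE)
  f_no <- fitCommS4(d, use_px = FALSE)
  expect_gte(elboFinal(f_px), elboFinal(f_no) - 1e-6)
  expect_lte(f_px@n_iter, f_no@n_iter)
})
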