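test_that("loglik kernel equals the dense joint density up to the dropped constant", {
  set.seed(101)
  for (m in c(1L, 2L, 4L, 6L)) {
    d <- rand_summary_data(m)
    g <- rnorm(m)
    p <- ModelParams(sigma2_gamma = runif(1, 0.05, 2),
                     alpha_prime = rnorm(1), tau = runif(1, 0.5, 2))
    expect_equal(loglikKernel(d, g, p) + dense_dropped_constant(d),
                 dense_joint_loglik(d, g, p), tolerance = 1e-10)
  }
})

test_that("loglik kernel degenerate and invariance cases", {
  d <- GeneSummaryData("g", 0, 0, diag(1), diag(1))
  expect_equal(loglikKernel(d, 0, ModelParams(sigma2_gamma = 1)),
               -0.5 * log(2 * pi))
  # with alpha' = 0 the GWAS LD matrix cannot matter
  set.seed(5)
  z1 <- rnorm(2); z2 <- rnorm(2); g <- rnorm(2)
  p <- ModelParams(sigma2_gamma = 0.5, alpha_prime = 0, tau = 1)
  dA <- GeneSummaryData("g", z1, z2, diag(2), diag(2))
  dB <- GeneSummaryData("g", z1, z2, diag(2), ar1_corr(2, 0.9))
  expect_identical(loglikKernel(dA, g, p), loglikKernel(dB, g, p))
  expect_error(loglikKernel(dA, c(1, 2, 3), p), "length")
  expect_error(loglikKernel(dA, c(NaN, 1), p), "finite")
})

test_that("exact marginal matches hand and quadrature oracles", {
  # m = 1: closed form of the 2-d normal written out by hand
  d1 <- GeneSummaryData("g", 1.5, 0.7, diag(1), diag(1))
  p1 <- ModelParams(sigma2_gamma = 0.6, alpha_prime = 0.9, tau = 1.2)
  S <- matrix(c(1 + p1@tau^2 * 0.6, p1@tau * 0.9 * 0.6,
                p1@tau * 0.9 * 0.6, 1 + 0.81 * 0.6), 2, 2)
  x <- c(1.5, 0.7)
  by_hand <- -0.5 * drop(x %*% solve(S, x)) - 0.5 * log(det(S)) - log(2 * pi)
  expect_equal(exactMarginalLoglik(d1, p1), by_hand, tolerance = 1e-12)

  # m = 1: adaptive quadrature over the latent effect
  f <- function(g) {
    vapply(g, function(gg) exp(dense_joint_loglik(d1, gg, p1)), numeric(1))
  }
  expect_equal(exactMarginalLoglik(d1, p1),
               log(integrate(f, -10, 10, rel.tol = 1e-10)$value),
               tolerance = 1e-7)

  # m = 3: Monte Carlo integration of the complete-data likelihood
  set.seed(202)
  d3 <- rand_summary_data(3)
  p3 <- ModelParams(sigma2_gamma = 0.8, alpha_prime = 0.4, tau = 1)
  G <- matrix(rnorm(2e5 * 3, 0, sqrt(p3@sigma2_gamma)), ncol = 3)
  lw <- apply(G, 1L, function(g) {
    dense_joint_loglik(d3, g, p3) -
      ldmvn(g, rep(0, 3), p3@sigma2_gamma * diag(3))
  })
  mc <- log(mean(exp(lw - max(lw)))) + max(lw)
  expect_equal(exactMarginalLoglik(d3, p3), mc, tolerance = 0.02)
})

test_that("exact marginal limits and symmetries", {
  set.seed(303)
  m <- 3L
  z1 <- rnorm(m); z2 <- rnorm(m)
  d <- GeneSummaryData("g", z1, z2, diag(m), diag(m))
  # vanishing prior variance: z-scores become independent standard normals
  p0 <- ModelParams(sigma2_gamma = 1e-8, alpha_prime = 0.7, tau = 1)
  expect_equal(exactMarginalLoglik(d, p0),
               sum(dnorm(c(z1, z2), log = TRUE)), tolerance = 1e-6)
  # flipping (alpha', tau) together with the z-score signs changes nothing
  dc <- rand_summary_data(m)
  p <- ModelParams(sigma2_gamma = 0.5, alpha_prime = 0.8, tau = 1.1)
  pneg <- ModelParams(sigma2_gamma = 0.5, alpha_prime = -0.8, tau = -1.1)
  expect_equal(exactMarginalLoglik(dc, p), exactMarginalLoglik(dc, pneg),
               tolerance = 1e-12)
  # at alpha' = 0 the GWAS block decouples: total is the sum of the two
  # independent marginals
  pnull <- ModelParams(sigma2_gamma = 0.5, alpha_prime = 0, tau = 1.1)
  only_eqtl <- ldmvn(eqtlZ(dc), rep(0, m),
                     ldEqtl(dc) + 1.1^2 * 0.5 * ldEqtl(dc) %*% ldEqtl(dc))
  only_gwas <- ldmvn(gwasZ(dc), rep(0, m), ldGwas(dc))
  expect_equal(exactMarginalLoglik(dc, pnull), only_eqtl + only_gwas,
               tolerance = 1e-10)
})

test_that("the low-rank marginal identity matches the dense computation", {
  set.seed(404)
  for (i in 1:6) {
    m <- sample(1:8, 1)
    d <- rand_summary_data(m)
    p <- ModelParams(runif(1, 0.01, 3), rnorm(1), runif(1, 0.5, 1.5))
    fast <- stwas:::.rss_marginal_dropped(eqtlZ(d), gwasZ(d), ldEqtl(d),
                                          ldGwas(d), p@sigma2_gamma,
                                          p@alpha_prime, p@tau)
    expect_equal(fast, exactMarginalLoglik(d, p, drop_constant = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("scale constant c follows the stated simple-regression formula", {
  expect_equal(computeCj(GeneScale(1, 1, 100, 100)), 1)
  expect_equal(computeCj(GeneScale(2, 1, 100, 400)), 4)
  expect_equal(computeCj(GeneScale(1.5, 3, 500, 10000)), 0.5 * sqrt(20))
  expect_error(GeneScale(-1, 1, 10, 10), "positive")
  expect_error(GeneScale(1, 1, 0, 10), "positive")
})

test_that("summary bundle validity catches malformed inputs", {
  expect_error(GeneSummaryData("g", c(1, 2), 1, diag(2), diag(2)), "differ")
  expect_error(GeneSummaryData("g", 1, 1, matrix(2, 1, 1), diag(1)),
               "diagonal")
  R <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(GeneSummaryData("g", c(1, 1), c(1, 1), R, diag(2)),
               "symmetric")
  expect_error(ModelParams(sigma2_gamma = 1, alpha_prime = NA), "finite")
})
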