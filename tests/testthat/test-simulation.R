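test_that("genotypes honour HWE frequencies and the latent AR correlation", {
  set.seed(121)
  n <- 20000
  maf <- c(0.1, 0.3, 0.45)
  G <- simulateGenotypes(n, 3, rho = 0, maf = maf)
  for (k in 1:3) {
    f <- maf[k]
    expected <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    observed <- tabulate(G[, k] + 1, nbins = 3) / n
    # 3 sigma binomial band per genotype class
    expect_true(all(abs(observed - expected) <
                      3 * sqrt(expected * (1 - expected) / n)))
  }
  # rho = 0: genotype columns essentially uncorrelated
  expect_lt(max(abs(cor(G)[upper.tri(diag(3))])), 0.02)

  # rho = 0.8: positive genotype correlation decaying with distance
  G8 <- simulateGenotypes(20000, 5, rho = 0.8)
  cg <- cor(G8)
  expect_gt(cg[1, 2], cg[1, 4])
  expect_gt(cg[1, 2], 0.4)
  # the latent AR process itself has adjacent correlation rho
  set.seed(5); X <- matrix(rnorm(20000 * 2), ncol = 2)
  X[, 2] <- 0.8 * X[, 1] + sqrt(1 - 0.64) * X[, 2]
  expect_equal(cor(X)[1, 2], 0.8, tolerance = 0.02)

  expect_identical(simulateGenotypes(50, 4, 0.5, seed = 9),
                   simulateGenotypes(50, 4, 0.5, seed = 9))
  expect_error(simulateGenotypes(10, 2, 1.5), "rho")
})

test_that("spike-and-slab effects have the right sparsity and are never all zero", {
  expect_true(all(simulateEffects(20, 1, seed = 1) != 0))
  set.seed(131)
  counts <- replicate(200, sum(simulateEffects(100, 0.1) != 0))
  expect_gt(mean(counts), 10 - 3 * sqrt(9 / 200))
  expect_lt(mean(counts), 10 + 3 * sqrt(9 / 200))
  expect_true(all(counts >= 1))
  expect_identical(simulateEffects(30, 0.2, seed = 7),
                   simulateEffects(30, 0.2, seed = 7))
})

test_that("expression and trait heritabilities are calibrated in realized variances", {
  set.seed(141)
  W <- simulateGenotypes(4000, 20, rho = 0.3)
  gamma <- simulateEffects(20, 0.5)
  g <- as.vector(W %*% gamma)

  ex <- simulateExpression(W, gamma, h_cell = 0.5)
  expect_equal(ex$sigma_e1^2, var(g), tolerance = 1e-12)  # h=0.5: equal parts
  r2 <- summary(lm(ex$y ~ g))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.05)
  ex0 <- simulateExpression(W, gamma, h_cell = 0)
  expect_lt(abs(cor(ex0$y, g)), 3 / sqrt(4000))
  expect_equal(ex0$sigma_e1, 1)

  tr <- simulateTrait(W, gamma, h_trait = 0.01)
  share <- var(tr$alpha * g) / (var(tr$alpha * g) + 1)
  expect_equal(share, 0.01, tolerance = 1e-12)
  tr0 <- simulateTrait(W, gamma, h_trait = 0)
  expect_identical(tr0$alpha, 0)
  # doubling the effects halves alpha but leaves the heritability alone
  tr2 <- simulateTrait(W, 2 * gamma, h_trait = 0.01)
  expect_equal(tr2$alpha, tr$alpha / 2, tolerance = 1e-12)
})

test_that("per-SNP regression summary statistics match a textbook OLS oracle", {
  set.seed(151)
  W <- matrix(rbinom(30, 2, 0.4), 10, 3)
  while (any(apply(W, 2, var) == 0)) W <- matrix(rbinom(30, 2, 0.4), 10, 3)
  y <- rnorm(10)
  ss <- summaryStats(y, W)
  for (k in 1:3) {
    fit <- summary(lm(y ~ W[, k]))
    expect_equal(ss$beta[k], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(ss$se[k], fit$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(ss$z[k], fit$coefficients[2, 3], tolerance = 1e-10)
  }
  expect_equal(ss$sd_outcome, sd(y))
  # perfect-fit column is refused (or flagged with a sentinel)
  expect_error(summaryStats(W[, 1], W), "perfect fit")
  sent <- summaryStats(W[, 1], W, perfect_fit = "sentinel")
  expect_equal(abs(sent$z[1]), 1e6)
  expect_error(summaryStats(y, cbind(W, 1)), "zero-variance")

  # no signal: z-scores are standard normal across SNPs
  set.seed(152)
  Wn <- simulateGenotypes(5000, 40, rho = 0)
  zn <- summaryStats(rnorm(5000), Wn)$z
  expect_gt(ks.test(zn, "pnorm")$p.value, 0.01)
})

test_that("worlds are reproducible and scenario nesting holds", {
  cfg <- scenarioConfig(n_eqtl = 200, n_gwas = 300, n_ref_eqtl = 100,
                        n_ref_gwas = 100, m = 25, h_cell = 0.05,
                        h_trait = 0.003, sparsity = 0.2)
  w1 <- buildWorld(cfg, rep_seed = 42)
  w2 <- buildWorld(cfg, rep_seed = 42)
  expect_identical(w1$W1, w2$W1)
  expect_identical(eqtlZ(w1$summary), eqtlZ(w2$summary))
  expect_true(all(w1$W1 %in% 0:2))
  # realized minor-allele frequencies stay inside the admissible band
  expect_true(all(colMeans(w1$W2) / 2 >= 0.01 & colMeans(w1$W2) / 2 <= 0.55))

  # full overlap reduces the distinct-architecture scenario to distinct-LD
  cfg2 <- scenarioConfig(n_eqtl = 200, n_gwas = 300, n_ref_eqtl = 100,
                         n_ref_gwas = 100, m = 25, h_cell = 0.05,
                         h_trait = 0.003, sparsity = 0.2,
                         ld_scenario = "distinct_ld")
  cfg3 <- scenarioConfig(n_eqtl = 200, n_gwas = 300, n_ref_eqtl = 100,
                         n_ref_gwas = 100, m = 25, h_cell = 0.05,
                         h_trait = 0.003, sparsity = 0.2,
                         ld_scenario = "distinct_ld_and_architecture",
                         overlap_fraction = 1)
  wa <- buildWorld(cfg2, rep_seed = 7)
  wb <- buildWorld(cfg3, rep_seed = 7)
  expect_identical(wa$gamma_gwas, wb$gamma_gwas)
  expect_identical(gwasZ(wa$summary), gwasZ(wb$summary))
  # partial overlap really changes the GWAS-side architecture
  cfg4 <- scenarioConfig(n_eqtl = 200, n_gwas = 300, n_ref_eqtl = 100,
                         n_ref_gwas = 100, m = 25, h_cell = 0.05,
                         h_trait = 0.003, sparsity = 0.2,
                         ld_scenario = "distinct_ld_and_architecture",
                         overlap_fraction = 0.5)
  wc <- buildWorld(cfg4, rep_seed = 7)
  expect_false(identical(which(wc$gamma_gwas != 0),
                         which(wc$gamma_true != 0)))

  # the two panels of a shared world estimate the same correlation matrix
  cfg5 <- scenarioConfig(n_eqtl = 50, n_gwas = 50, n_ref_eqtl = 4000,
                         n_ref_gwas = 4000, m = 10, h_cell = 0.05,
                         h_trait = 0, sparsity = 0.5)
  wd <- buildWorld(cfg5, rep_seed = 9)
  expect_lt(max(abs(ldEqtl(wd$summary) - ldGwas(wd$summary))), 0.1)

  # a full-size world builds quickly
  t0 <- Sys.time()
  buildWorld(scenarioConfig(), rep_seed = 1)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
})

test_that("the power harness aggregates rejections over the grid", {
  cfg <- scenarioConfig(n_eqtl = 300, n_gwas = 400, n_ref_eqtl = 150,
                        n_ref_gwas = 150, m = 15, rho = 0.5, sparsity = 0.3,
                        h_cell = c(0.05, 0.3), h_trait = c(0, 0.05),
                        n_reps = 8, seed = 77)
  tab <- suppressWarnings(powerExperiment(cfg, methods = "comm_s4"))
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$power >= 0 & tab$power <= 1))
  expect_true(all(tab$n_reps == 8))
  expect_named(tab, c("scenario", "h_cell", "sparsity", "h_trait", "method",
                      "n_reps", "power", "mc_se"))
  # strong signal cell dominates the matching null cell
  strong <- tab$power[tab$h_cell == 0.3 & tab$h_trait == 0.05]
  null_ <- tab$power[tab$h_cell == 0.3 & tab$h_trait == 0]
  expect_gte(strong, null_)
  # deterministic under the same master seed
  tab2 <- suppressWarnings(powerExperiment(cfg, methods = "comm_s4"))
  expect_identical(tab$power, tab2$power)
})
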