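# Generative model for linked eQTL / GWAS worlds and the power, type-I-error
# and concordance experiment harnesses.
#
# Genotypes arise from a latent Gaussian with AR-1 correlation thresholded to
# Hardy-Weinberg genotype frequencies at per-SNP minor allele frequencies
# drawn from U(0.05, 0.5). Expression is y = W1 gamma + e1 with spike-and-slab
# effects and noise calibrated to a target cellular heritability; the trait is
# z = alpha W2 gamma + e2 with unit noise and alpha calibrated to a target
# trait heritability. Summary statistics are per-SNP simple linear
# regressions, and LD matrices come from separate finite reference panels,
# exactly as the test would see them in practice.

#' Scenario configuration for the simulation harnesses
#'
#' Collects every knob of the generative model and the experiment harnesses.
#' The defaults are the power-study conditions: eQTL study of 500 samples,
#' GWAS of 10,000, reference panels of 400 each, 100 cis-SNPs with AR-1
#' latent correlation 0.5, sparsity 0.1, cellular heritability 0.01 and trait
#' heritability 0.003, tested at level 0.05.
#'
#' @param n_eqtl,n_gwas eQTL and GWAS sample sizes.
#' @param n_ref_eqtl,n_ref_gwas reference panel sizes.
#' @param m number of cis-SNPs.
#' @param rho latent AR-1 correlation between adjacent SNPs (eQTL side).
#' @param sparsity probability a SNP has a nonzero effect on expression; may
#'   be a vector for grid experiments.
#' @param h_cell cellular heritability (expression variance explained by
#'   genotype); may be a vector.
#' @param h_trait trait heritability through the gene; may be a vector; 0 is
#'   the null.
#' @param ld_scenario `"shared"` (one population law for everything),
#'   `"distinct_ld"` (eQTL and GWAS sides get independent laws with
#'   different `rho`), or `"distinct_ld_and_architecture"` (additionally the
#'   GWAS-side causal set only partially overlaps the eQTL one).
#' @param rho_gwas GWAS-side AR-1 correlation for the distinct-LD scenarios;
#'   default picks 0.8 (or 0.5 when `rho` is already 0.8).
#' @param overlap_fraction fraction of the eQTL causal set retained on the
#'   GWAS side in the `distinct_ld_and_architecture` scenario.
#' @param shrinkage LD shrinkage used on the simulated panels.
#' @param n_reps replicates per grid cell.
#' @param seed master seed for the experiment harnesses.
#' @param alpha_level nominal level for power and type-I-error rates.
#' @return a list of class `ScenarioConfig`.
#' @export
scenarioConfig <- function(n_eqtl = 500, n_gwas = 10000, n_ref_eqtl = 400,
                           n_ref_gwas = 400, m = 100, rho = 0.5,
                           sparsity = 0.1, h_cell = 0.01, h_trait = 0.003,
                           ld_scenario = c("shared", "distinct_ld",
                                           "distinct_ld_and_architecture"),
                           rho_gwas = NULL, overlap_fraction = 0.5,
                           shrinkage = 0.05, n_reps = 500, seed = 1,
                           alpha_level = 0.05) {
  ld_scenario <- match.arg(ld_scenario)
  stopifnot(n_eqtl >= 2, n_gwas >= 2, n_ref_eqtl >= 2, n_ref_gwas >= 2,
            m >= 1, abs(rho) < 1,
            all(sparsity > 0), all(sparsity <= 1),
            all(h_cell >= 0), all(h_cell < 1),
            all(h_trait >= 0), all(h_trait < 1),
            overlap_fraction >= 0, overlap_fraction <= 1,
            alpha_level > 0, alpha_level < 1, n_reps >= 1)
  if (is.null(rho_gwas)) rho_gwas <- if (rho == 0.8) 0.5 else 0.8
  structure(list(
    n_eqtl = n_eqtl, n_gwas = n_gwas, n_ref_eqtl = n_ref_eqtl,
    n_ref_gwas = n_ref_gwas, m = m, rho = rho, sparsity = sparsity,
    h_cell = h_cell, h_trait = h_trait, ld_scenario = ld_scenario,
    rho_gwas = rho_gwas, overlap_fraction = overlap_fraction,
    shrinkage = shrinkage, n_reps = n_reps, seed = seed,
    alpha_level = alpha_level), class = "ScenarioConfig")
}

#' Simulate HWE genotypes with AR-1 latent correlation
#'
#' Each sample's latent row is a stationary AR-1 Gaussian process across SNP
#' positions (`Cov(x_k, x_l) = rho^|k-l|`). Per-SNP minor allele frequencies
#' `f` are drawn from U(0.05, 0.5) (or supplied), and the latent values are
#' cut at the standard-normal quantiles of `(1-f)^2` and `(1-f)^2 + 2f(1-f)`
#' to assign dosages 0/1/2, so each SNP has Hardy-Weinberg genotype
#' frequencies at its `f`.
#'
#' @param n samples.
#' @param m SNPs.
#' @param rho AR-1 correlation, `|rho| < 1`.
#' @param maf optional vector of minor allele frequencies; drawn if `NULL`.
#' @param seed optional seed.
#' @return an `n x m` matrix with entries 0/1/2 and attribute `"maf"`.
#' @export
simulateGenotypes <- function(n, m, rho, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, m >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  stopifnot(length(maf) == m, all(maf > 0), all(maf < 1))
  X <- matrix(rnorm(n * m), n, m)
  if (rho != 0 && m > 1) {
    w <- sqrt(1 - rho^2)
    for (k in 2:m) X[, k] <- rho * X[, k - 1] + w * X[, k]
  }
  p0 <- (1 - maf)^2
  q1 <- qnorm(p0)
  q2 <- qnorm(p0 + 2 * maf * (1 - maf))
  G <- matrix(0, n, m)
  for (k in seq_len(m)) {
    G[, k] <- (X[, k] > q1[k]) + (X[, k] > q2[k])
  }
  attr(G, "maf") <- maf
  G
}

#' Spike-and-slab effect sizes
#'
#' Each entry is standard normal with probability `sparsity` and exactly zero
#' otherwise; the all-zero outcome is redrawn (heritability would be
#' undefined).
#'
#' @param m number of SNPs.
#' @param sparsity inclusion probability in (0, 1\].
#' @param seed optional seed.
#' @return numeric vector of length `m` with at least one nonzero entry.
#' @export
simulateEffects <- function(m, sparsity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sparsity > 0, sparsity <= 1)
  repeat {
    gamma <- rnorm(m) * rbinom(m, 1, sparsity)
    if (any(gamma != 0)) return(gamma)
  }
}

#' Simulate expression at a target cellular heritability
#'
#' Noise variance is chosen from the realized genetic variance:
#' `sigma_e1^2 = var(W1 gamma) (1 - h) / h`, so the heritability holds
#' exactly in terms of empirical variances. `h_cell = 0` yields pure
#' unit-variance noise (zero genetic signal).
#'
#' @param W1 eQTL genotype matrix.
#' @param gamma effect vector.
#' @param h_cell target heritability in \[0, 1).
#' @param seed optional seed.
#' @return list with `y`, `sigma_e1` and the genetic component `signal`.
#' @export
simulateExpression <- function(W1, gamma, h_cell, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(h_cell >= 0, h_cell < 1)
  n <- nrow(W1)
  if (h_cell == 0) {
    return(list(y = rnorm(n), sigma_e1 = 1, signal = rep(0, n)))
  }
  g <- as.vector(W1 %*% gamma)
  vg <- var(g)
  if (vg == 0) stop("genetic component is constant but h_cell > 0")
  sigma_e1 <- sqrt(vg * (1 - h_cell) / h_cell)
  list(y = g + rnorm(n, 0, sigma_e1), sigma_e1 = sigma_e1, signal = g)
}

#' Simulate a trait at a target heritability through the gene
#'
#' With unit noise variance, the expression-on-trait coefficient is scaled so
#' that `var(alpha W2 gamma) / (var(alpha W2 gamma) + 1) = h_trait` in
#' realized variances. `h_trait = 0` is the null (`alpha = 0`).
#'
#' @param W2 GWAS genotype matrix.
#' @param gamma effect vector (GWAS-side architecture).
#' @param h_trait target trait heritability in \[0, 1).
#' @param seed optional seed.
#' @return list with `z`, `alpha` and `sigma_e2 = 1`.
#' @export
simulateTrait <- function(W2, gamma, h_trait, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(h_trait >= 0, h_trait < 1)
  n <- nrow(W2)
  if (h_trait == 0) {
    return(list(z = rnorm(n), alpha = 0, sigma_e2 = 1))
  }
  g <- as.vector(W2 %*% gamma)
  vg <- var(g)
  if (vg == 0) stop("genetic component is constant but h_trait > 0")
  alpha <- sqrt(h_trait / ((1 - h_trait) * vg))
  list(z = alpha * g + rnorm(n), alpha = alpha, sigma_e2 = 1)
}

#' Per-SNP simple-linear-regression summary statistics
#'
#' Regresses the outcome on each (centered) genotype column separately with
#' an intercept, returning the slope, its OLS standard error (n - 2 df) and
#' the z-score `beta / se`.
#'
#' @param outcome numeric outcome vector.
#' @param W genotype matrix, samples by SNPs.
#' @param perfect_fit what to do when a SNP explains the outcome exactly:
#'   `"error"` (default) or `"sentinel"` (return z = +/- 1e6).
#' @return list with `z`, `se`, `beta` and `sd_outcome`.
#' @export
summaryStats <- function(outcome, W, perfect_fit = c("error", "sentinel")) {
  perfect_fit <- match.arg(perfect_fit)
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(length(outcome) == n, n > 2)
  yc <- outcome - mean(outcome)
  Wc <- sweep(W, 2L, colMeans(W))
  sxx <- colSums(Wc^2)
  if (any(sxx == 0)) {
    stop("zero-variance SNP at column ", which(sxx == 0)[1L])
  }
  sxy <- as.vector(crossprod(Wc, yc))
  beta <- sxy / sxx
  rss <- pmax(sum(yc^2) - beta^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  bad <- se == 0
  if (any(bad)) {
    if (perfect_fit == "error") {
      stop("perfect fit (zero residual variance) at column ", which(bad)[1L])
    }
    z <- beta / se
    z[bad] <- sign(beta[bad]) * 1e6
  } else {
    z <- beta / se
  }
  list(z = z, se = se, beta = beta, sd_outcome = sd(outcome))
}

# GWAS-side causal architecture for the partial-overlap scenario: keep
# round(overlap * K) of the K eQTL causal SNPs, replace the rest with new
# causal SNPs drawn from the non-causal positions, effects from the same slab.
.partial_overlap_effects <- function(gamma, overlap) {
  causal <- which(gamma != 0)
  K <- length(causal)
  n_keep <- round(overlap * K)
  gamma2 <- gamma
  drop <- if (n_keep < K) {
    sample(causal, K - n_keep)
  } else {
    integer(0)
  }
  gamma2[drop] <- 0
  pool <- setdiff(seq_along(gamma), causal)
  n_new <- min(K - n_keep, length(pool))
  if (n_new > 0) {
    newpos <- sample(pool, n_new)
    gamma2[newpos] <- rnorm(n_new)
  }
  if (all(gamma2 == 0)) gamma2[sample(seq_along(gamma2), 1L)] <- rnorm(1)
  gamma2
}

#' Build one simulated eQTL/GWAS world
#'
#' Draws genotypes for the eQTL study, the GWAS, and the two reference
#' panels; draws the causal architecture; generates expression and trait at
#' the configured heritabilities; computes per-SNP simple-regression summary
#' statistics on both sides and shrunk LD matrices from the panels; and
#' assembles the per-gene summary bundle exactly as the association test
#' would receive it.
#'
#' In the `shared` scenario all four genotype matrices are independent draws
#' from one population law (one MAF vector, one `rho`). In `distinct_ld` the
#' GWAS side (study and panel) gets its own MAF vector and `rho_gwas`. In
#' `distinct_ld_and_architecture` the GWAS-side causal set additionally keeps
#' only `overlap_fraction` of the eQTL causal SNPs, the remainder replaced by
#' fresh causal SNPs of matched effect variance.
#'
#' @param config a [scenarioConfig()] list; scalar `h_cell`, `h_trait`,
#'   `sparsity` are used.
#' @param rep_seed seed for this replicate; defaults to `config$seed`.
#' @return a list of class `SimulatedWorld` with elements `W1`, `W2`,
#'   `panel1`, `panel2`, `gamma_true`, `gamma_gwas`, `y`, `z`, `alpha_true`,
#'   `sigma_e1`, `sigma_e2`, `summary` ([GeneSummaryData-class]) and `scale`
#'   ([GeneScale-class]).
#' @export
buildWorld <- function(config, rep_seed = config$seed) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(rep_seed)
  m <- config$m
  h_cell <- config$h_cell[1L]
  h_trait <- config$h_trait[1L]
  sparsity <- config$sparsity[1L]
  snp_ids <- paste0("snp", seq_len(m))

  maf1 <- runif(m, 0.05, 0.5)
  distinct <- config$ld_scenario != "shared"
  maf2 <- if (distinct) runif(m, 0.05, 0.5) else maf1
  rho2 <- if (distinct) config$rho_gwas else config$rho

  W1 <- simulateGenotypes(config$n_eqtl, m, config$rho, maf = maf1)
  P1 <- simulateGenotypes(config$n_ref_eqtl, m, config$rho, maf = maf1)
  W2 <- simulateGenotypes(config$n_gwas, m, rho2, maf = maf2)
  P2 <- simulateGenotypes(config$n_ref_gwas, m, rho2, maf = maf2)

  gamma <- simulateEffects(m, sparsity)
  gamma_gwas <- if (config$ld_scenario == "distinct_ld_and_architecture") {
    .partial_overlap_effects(gamma, config$overlap_fraction)
  } else {
    gamma
  }

  expr <- simulateExpression(W1, gamma, h_cell)
  trait <- simulateTrait(W2, gamma_gwas, h_trait)

  ss1 <- summaryStats(expr$y, W1)
  ss2 <- summaryStats(trait$z, W2)
  panel1 <- GenotypePanel(P1, snp_ids = snp_ids)
  panel2 <- GenotypePanel(P2, snp_ids = snp_ids)

  summary <- GeneSummaryData(
    gene_id = sprintf("sim_seed%d", rep_seed),
    eqtl_z = ss1$z, gwas_z = ss2$z,
    ld_eqtl = estimateLD(panel1, shrinkage = config$shrinkage),
    ld_gwas = estimateLD(panel2, shrinkage = config$shrinkage),
    snp_ids = snp_ids)

  structure(list(
    W1 = W1, W2 = W2, panel1 = panel1, panel2 = panel2,
    gamma_true = gamma, gamma_gwas = gamma_gwas,
    y = expr$y, z = trait$z, alpha_true = trait$alpha,
    sigma_e1 = expr$sigma_e1, sigma_e2 = trait$sigma_e2,
    summary = summary,
    scale = GeneScale(sd(expr$y), sd(trait$z), config$n_eqtl, config$n_gwas)
  ), class = "SimulatedWorld")
}

# Runs the requested methods on one world; returns named p-value vector with
# NA for a method that errored.
.run_methods <- function(world, methods, cv_seed = 1L) {
  out <- setNames(rep(NA_real_, length(methods)), methods)
  ind <- NULL
  need_ind <- any(methods %in% c("comm_s2", "ridge", "enet"))
  if (need_ind) {
    ind <- IndividualEqtlData(
      gene_id = geneId(world$summary), y = world$y, genotypes = world$W1,
      gwas_z = gwasZ(world$summary), ld_gwas = ldGwas(world$summary),
      panel_sd = apply(world$panel2@genotypes, 2L, sd),
      snp_ids = snpIds(world$summary))
  }
  for (mth in methods) {
    p <- tryCatch(switch(mth,
      comm_s4 = pValue(lrtTest(world$summary)),
      comm_s2 = pValue(commS2Test(ind)),
      ridge = pValue(twoStageTwas(ind, predictor = "ridge", seed = cv_seed)),
      enet = pValue(twoStageTwas(ind, predictor = "elastic_net",
                                 seed = cv_seed)),
      stop("unknown method: ", mth)
    ), error = function(e) {
      message(sprintf("method %s failed: %s", mth, conditionMessage(e)))
      NA_real_
    })
    out[mth] <- p
  }
  out
}

#' Power / type-I-error experiment
#'
#' For every cell of the `h_cell` x `sparsity` x `h_trait` grid in the
#' configuration, simulates `n_reps` worlds, runs the requested methods, and
#' records the fraction of replicates rejected at `alpha_level` with its
#' Monte Carlo standard error. Cells with `h_trait = 0` measure type-I error;
#' cells with `h_trait > 0` measure power. A method failure on a replicate
#' counts as a non-rejection (with a message).
#'
#' @param config a [scenarioConfig()] list; `h_cell`, `sparsity`, `h_trait`
#'   may be vectors defining the grid.
#' @param methods subset of `c("comm_s4", "comm_s2", "ridge", "enet")`.
#' @return a `data.frame` with columns scenario, h_cell, sparsity, h_trait,
#'   method, n_reps, power, mc_se.
#' @export
powerExperiment <- function(config, methods = "comm_s4") {
  stopifnot(inherits(config, "ScenarioConfig"), length(methods) >= 1)
  grid <- expand.grid(h_cell = config$h_cell, sparsity = config$sparsity,
                      h_trait = config$h_trait, KEEP.OUT.ATTRS = FALSE)
  set.seed(config$seed)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, nrow(grid) * config$n_reps),
    nrow(grid), config$n_reps)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- scenarioConfig(
      n_eqtl = config$n_eqtl, n_gwas = config$n_gwas,
      n_ref_eqtl = config$n_ref_eqtl, n_ref_gwas = config$n_ref_gwas,
      m = config$m, rho = config$rho, sparsity = grid$sparsity[i],
      h_cell = grid$h_cell[i], h_trait = grid$h_trait[i],
      ld_scenario = config$ld_scenario, rho_gwas = config$rho_gwas,
      overlap_fraction = config$overlap_fraction,
      shrinkage = config$shrinkage, n_reps = config$n_reps,
      seed = config$seed, alpha_level = config$alpha_level)
    rej <- matrix(FALSE, config$n_reps, length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(config$n_reps)) {
      world <- buildWorld(cell, rep_seed = seeds[i, r])
      p <- .run_methods(world, methods, cv_seed = seeds[i, r])
      rej[r, ] <- !is.na(p) & p < config$alpha_level
    }
    pow <- colMeans(rej)
    rows[[i]] <- data.frame(
      scenario = config$ld_scenario, h_cell = grid$h_cell[i],
      sparsity = grid$sparsity[i], h_trait = grid$h_trait[i],
      method = methods, n_reps = config$n_reps, power = unname(pow),
      mc_se = unname(sqrt(pow * (1 - pow) / config$n_reps)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Concordance between the summary-level and individual-level tests
#'
#' Simulates worlds (by default at the concordance-study sizes, 5,000 eQTL
#' and 5,000 GWAS samples), computes on each world both the summary-level
#' statistic and the individual-level-eQTL comparator statistic, pools the
#' pairs over the cellular-heritability grid (0.01, 0.03, 0.05, 0.07, 0.09)
#' crossed with trait heritabilities (0.001, 0.002, 0.003), and regresses
#' the comparator statistic on the summary-level one by ordinary least
#' squares.
#'
#' @param config a [scenarioConfig()] list; `n_reps` is the total number of
#'   pooled replicates, spread round-robin over the grid; `h_cell` and
#'   `h_trait` define the pooled grid.
#' @return a list with `r_squared`, `slope` and the `pairs` data frame
#'   (columns lrt_s4, lrt_s2, h_cell, h_trait).
#' @export
concordanceExperiment <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"), config$n_reps >= 2)
  grid <- expand.grid(h_cell = config$h_cell, h_trait = config$h_trait,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  cells <- rep_len(seq_len(nrow(grid)), config$n_reps)
  lrt_s4 <- lrt_s2 <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    i <- cells[r]
    cell <- scenarioConfig(
      n_eqtl = config$n_eqtl, n_gwas = config$n_gwas,
      n_ref_eqtl = config$n_ref_eqtl, n_ref_gwas = config$n_ref_gwas,
      m = config$m, rho = config$rho, sparsity = config$sparsity[1L],
      h_cell = grid$h_cell[i], h_trait = grid$h_trait[i],
      ld_scenario = config$ld_scenario, rho_gwas = config$rho_gwas,
      overlap_fraction = config$overlap_fraction,
      shrinkage = config$shrinkage, n_reps = 1L, seed = config$seed,
      alpha_level = config$alpha_level)
    world <- buildWorld(cell, rep_seed = seeds[r])
    lrt_s4[r] <- lrtStat(lrtTest(world$summary))
    ind <- IndividualEqtlData(
      gene_id = geneId(world$summary), y = world$y, genotypes = world$W1,
      gwas_z = gwasZ(world$summary), ld_gwas = ldGwas(world$summary),
      panel_sd = apply(world$panel2@genotypes, 2L, sd),
      snp_ids = snpIds(world$summary))
    lrt_s2[r] <- lrtStat(commS2Test(ind))
  }
  pairs <- data.frame(lrt_s4 = lrt_s4, lrt_s2 = lrt_s2,
                      h_cell = grid$h_cell[cells],
                      h_trait = grid$h_trait[cells])
  fit <- lm(lrt_s2 ~ lrt_s4, data = pairs)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2L]),
       pairs = pairs)
}
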