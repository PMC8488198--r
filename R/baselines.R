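# Comparator methods: the individual-level-eQTL likelihood-ratio test and
# two-stage predict-then-associate tests (ridge / elastic net) driven by a
# weighted summary-statistic z-score.

# Constant-dropped exact marginal log-likelihood for the individual-level
# arm, by the same Woodbury / determinant-lemma route as the summary model:
# with R = blockdiag(sigma2e I_n, R2) and C = rbind(X, alpha R2), the joint
# covariance of (y, z2) is R + sigma2 C C', so everything reduces to
# M = I + sigma2 ((1/sigma2e) X'X + alpha^2 R2) and
# u = X'y / sigma2e + alpha z2. The y-arm terms depend on sigma2e and are
# kept; only the GWAS-arm constants (z2' R2^{-1} z2, log|2 pi R2|) drop.
.ind_marginal_dropped <- function(xtx, xty, yty, n, z2, R2, sigma2, alpha,
                                  sigma2e) {
  m <- ncol(xtx)
  M <- diag(m) + sigma2 * (xtx / sigma2e + alpha^2 * R2)
  u <- xty / sigma2e + alpha * z2
  ch <- chol(M)
  -n / 2 * log(2 * pi * sigma2e) - yty / (2 * sigma2e) +
    0.5 * sigma2 * sum(backsolve(ch, u, transpose = TRUE)^2) -
    sum(log(diag(ch)))
}

# ELBO for the individual-level eQTL arm + summary GWAS arm, with the GWAS
# parameter-free constants dropped (the eQTL arm is a complete Gaussian
# likelihood, nothing to drop there).
.elbo_ind <- function(yty, xty, xtx_diag, quad_xtx, n, z2, R2, mu, s2,
                      sigma2e, sg2, a, tau) {
  equad_x <- quad_xtx + sum(xtx_diag * s2)
  equad_r2 <- sum(mu * (R2 %*% mu)) + sum(diag(R2) * s2)
  -n / 2 * log(2 * pi * sigma2e) -
    (yty - 2 * tau * sum(mu * xty) + tau^2 * equad_x) / (2 * sigma2e) +
    a * sum(z2 * mu) - a^2 / 2 * equad_r2 -
    sum(mu^2 + s2) / (2 * sg2) - length(mu) / 2 * log(2 * pi * sg2) +
    0.5 * sum(log(2 * pi * exp(1) * s2))
}

#' Likelihood-ratio test with individual-level eQTL data
#'
#' Comparator that keeps the GWAS arm of the summary-statistics model but
#' replaces the eQTL arm with the exact Gaussian likelihood of the observed
#' expression: `y | gamma ~ N(tau X gamma, sigma_e^2 I)` with
#' `X = W1_centered %*% diag(se1)`, where `se1` are the per-SNP marginal OLS
#' standard errors, so the latent effects stay on the same standardized scale
#' as in the summary-level model and the two likelihood-ratio statistics are
#' directly comparable. Fitted by the same parameter-expanded mean-field
#' coordinate ascent, with the residual variance `sigma_e^2` as an additional
#' free parameter; tested against a chi-squared with one degree of freedom.
#'
#' As in [lrtTest()], `statistic = "marginal"` (default) evaluates the exact
#' marginal log-likelihood of the fitted models — collapsed to `m x m`
#' arithmetic through a Woodbury identity, profiling
#' `(sigma2_gamma, alpha', sigma_e^2)` from the variational solution — while
#' `statistic = "elbo"` uses the variational bound difference directly.
#'
#' @param data an [IndividualEqtlData-class] object.
#' @param statistic `"marginal"` or `"elbo"`, as in [lrtTest()].
#' @param tol,max_iter,use_px convergence settings, as in [fitCommS4()].
#' @return a [TestResult-class] object (method `"comm_s2"`).
#' @export
commS2Test <- function(data, statistic = c("marginal", "elbo"), tol = 1e-6,
                       max_iter = 1000L, use_px = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(is(data, "IndividualEqtlData"))
  W <- data@genotypes
  n <- nrow(W)
  m <- ncol(W)
  y <- data@y - mean(data@y)
  se1 <- summaryStats(data@y, W)$se
  X <- sweep(sweep(W, 2L, colMeans(W)), 2L, se1, "*")
  xtx <- crossprod(X)
  xty <- as.vector(crossprod(X, y))
  yty <- sum(y^2)
  R2 <- data@ld_gwas
  z2 <- data@gwas_z

  fit_one <- function(null_model, init = NULL, init_q = NULL) {
    sg2 <- if (is.null(init)) 0.01 else init$sg2
    a <- if (null_model || is.null(init)) 0 else init$a
    tau <- 1
    sigma2e <- if (is.null(init)) var(y) else init$sigma2e
    mu <- if (is.null(init_q)) rep(0, m) else init_q$mu
    trace <- numeric(0)
    last <- -Inf
    converged <- FALSE
    it <- 0L
    s2 <- rep(sg2, m)
    quad <- function(A, v) sum(v * (A %*% v))
    while (it < max_iter) {
      it <- it + 1L
      sw <- .sweep_individual(xty, xtx, sigma2e, z2, R2, mu, sg2, a, tau)
      mu <- sw$mu
      s2 <- sw$s2
      quad_xtx <- quad(xtx, mu)
      trace <- c(trace, .elbo_ind(yty, xty, diag(xtx), quad_xtx, n, z2, R2,
                                  mu, s2, sigma2e, sg2, a, tau))
      sg2 <- max(mean(mu^2 + s2), .SIGMA2_FLOOR)
      equad_x <- quad_xtx + sum(diag(xtx) * s2)
      if (use_px && equad_x > .Machine$double.eps) {
        tau <- sum(mu * xty) / equad_x
      }
      if (!null_model) {
        den <- quad(R2, mu) + sum(diag(R2) * s2)
        if (den > .Machine$double.eps) a <- sum(z2 * mu) / den
      }
      sigma2e <- max((yty - 2 * tau * sum(mu * xty) + tau^2 * equad_x) / n,
                     1e-10)
      cur <- .elbo_ind(yty, xty, diag(xtx), quad_xtx, n, z2, R2, mu, s2,
                       sigma2e, sg2, a, tau)
      trace <- c(trace, cur)
      if (is.finite(last) && abs(cur - last) < tol * (1 + abs(last))) {
        converged <- TRUE
        last <- cur
        break
      }
      last <- cur
    }
    if (!converged) {
      warning(sprintf("individual-level fit did not converge in %d iterations",
                      max_iter))
    }
    # Map back to the reduced model (tau = 1); ELBO-invariant.
    if (tau != 0) {
      sg2r <- tau^2 * sg2
      ar <- if (null_model) 0 else a / tau
      mur <- tau * mu
      s2r <- tau^2 * s2
    } else {
      sg2r <- .SIGMA2_FLOOR; ar <- a; mur <- mu; s2r <- s2
    }
    list(fit = new("FitResult",
                   params = ModelParams(sigma2_gamma = sg2r, alpha_prime = ar,
                                        tau = 1, null_model = null_model),
                   posterior = VariationalPosterior(mur, s2r),
                   elbo = last, elbo_trace = trace, n_iter = it,
                   converged = converged),
         sigma2e = sigma2e)
  }

  res0 <- fit_one(TRUE)
  fit0 <- res0$fit
  res1 <- fit_one(FALSE,
                  init = list(sg2 = fit0@params@sigma2_gamma, a = 0,
                              sigma2e = res0$sigma2e),
                  init_q = list(mu = fit0@posterior@mu))
  fit1 <- res1$fit
  if (statistic == "elbo") {
    lrt_raw <- 2 * (fit1@elbo - fit0@elbo)
    a_hat <- fit1@params@alpha_prime
    s2_hat <- fit1@params@sigma2_gamma
  } else {
    obj0 <- function(th) {
      -.ind_marginal_dropped(xtx, xty, yty, n, z2, R2, exp(th[1L]), 0,
                             exp(th[2L]))
    }
    op0 <- optim(c(log(max(fit0@params@sigma2_gamma, 1e-8)),
                   log(res0$sigma2e)), obj0, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 2000))
    obj1 <- function(th) {
      -.ind_marginal_dropped(xtx, xty, yty, n, z2, R2, exp(th[1L]), th[2L],
                             exp(th[3L]))
    }
    best <- NULL
    for (s in list(c(log(max(fit1@params@sigma2_gamma, 1e-8)),
                     fit1@params@alpha_prime, log(res1$sigma2e)),
                   c(op0$par[1L], 0, op0$par[2L]))) {
      op <- tryCatch(optim(s, obj1, method = "Nelder-Mead",
                           control = list(reltol = 1e-10, maxit = 3000)),
                     error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    lrt_raw <- 2 * (-best$value + op0$value)
    a_hat <- best$par[2L]
    s2_hat <- max(exp(best$par[1L]), .SIGMA2_FLOOR)
  }
  .make_test_result(data@gene_id, lrt_raw,
                    alpha_prime_hat = a_hat, sigma2_hat = s2_hat,
                    n_snps = m, method = "comm_s2",
                    fit_null = fit0, fit_alt = fit1)
}

#' Two-stage predict-then-associate test
#'
#' Stage 1 fits a penalized regression of expression on the eQTL genotypes
#' (ridge, or elastic net with mixing parameter 0.5) with the penalty chosen
#' by 5-fold cross-validation. Stage 2 combines the prediction weights `w`
#' with the GWAS z-scores through the weighted summary statistic
#' `z = sum_k w_k sigma_k z2_k / sqrt(w' D R2 D w)` with
#' `D = diag(sigma_k)`, the reference-panel genotype standard deviations,
#' and refers it to a standard normal (two-sided). The statistic is
#' invariant to rescaling the expression vector. An all-zero weight vector
#' (elastic net can select nothing) yields p = 1 with a message.
#'
#' @param data an [IndividualEqtlData-class] object; its `panel_sd` slot
#'   provides `sigma_k`.
#' @param predictor `"ridge"` or `"elastic_net"`.
#' @param nfolds cross-validation folds for the penalty.
#' @param seed seed for the cross-validation fold assignment.
#' @return a [TestResult-class] object (`lrt_stat` holds `z^2`, so the
#'   chi-squared-1 p-value equals the two-sided normal one).
#' @export
twoStageTwas <- function(data, predictor = c("ridge", "elastic_net"),
                         nfolds = 5L, seed = 1L) {
  stopifnot(is(data, "IndividualEqtlData"))
  predictor <- match.arg(predictor)
  mix <- if (predictor == "ridge") 0 else 0.5
  if (ncol(data@genotypes) == 1L) {
    # degenerate single-predictor gene: plain OLS slope (the statistic is
    # invariant to the weight's scale anyway)
    x <- data@genotypes[, 1L]
    w <- cov(data@y, x) / var(x)
  } else {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x = data@genotypes, y = data@y, alpha = mix,
                            nfolds = nfolds, standardize = TRUE)
    w <- as.vector(coef(cv, s = "lambda.min"))[-1L]
  }
  method <- if (predictor == "ridge") "ridge" else "enet"
  if (all(w == 0)) {
    message("all prediction weights are zero; reporting p = 1")
    return(.make_test_result(data@gene_id, 0, alpha_prime_hat = 0,
                             sigma2_hat = NA_real_, n_snps = ncol(data@genotypes),
                             method = method))
  }
  ws <- w * data@panel_sd
  den <- sqrt(sum(ws * (data@ld_gwas %*% ws)))
  z <- sum(ws * data@gwas_z) / den
  .make_test_result(data@gene_id, z^2, alpha_prime_hat = z,
                    sigma2_hat = NA_real_, n_snps = ncol(data@genotypes),
                    method = method)
}
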