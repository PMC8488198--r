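# Parameter-dependent part of the joint summary-statistics log-likelihood and
# the closed-form Gaussian marginal used as an oracle.
#
# The model for one gene with m SNPs:
#   eqtl_z | gamma ~ N(tau * R1 %*% gamma, R1)
#   gwas_z | gamma ~ N(alpha' * R2 %*% gamma, R2)
#   gamma          ~ N(0, sigma2_gamma * I)
# with tau the redundant expansion parameter (tau = 1 in the reduced model).
# Every term that depends on neither gamma nor the parameters (the quadratic
# forms in R^{-1} and the log-determinants) is dropped throughout the package:
# those terms cancel in the likelihood-ratio statistic, and dropping them is
# what lets the fit avoid inverting the LD matrices.

#' Parameter-dependent part of the complete-data log-likelihood
#'
#' Evaluates the part of
#' `log Pr(eqtl_z, gwas_z, gamma | R1, R2; theta)` that depends on `gamma`
#' and on the parameters:
#' `tau * t(z1) %*% g - tau^2/2 * t(g) %*% R1 %*% g + alpha' * t(z2) %*% g -
#'  alpha'^2/2 * t(g) %*% R2 %*% g - t(g) %*% g / (2 s2) - m/2 log(2 pi s2)`.
#' Constant terms involving the LD-matrix inverses and determinants are
#' deliberately omitted; they cancel in the likelihood-ratio statistic.
#'
#' @param data a [GeneSummaryData-class] object.
#' @param gamma numeric vector of latent standardized effects, length `nSnps(data)`.
#' @param params a [ModelParams-class] object.
#' @return a single number.
#' @examples
#' d <- GeneSummaryData("g", 0, 0, diag(1), diag(1))
#' loglikKernel(d, 0, ModelParams(sigma2_gamma = 1))  # -log(2*pi)/2
#' @export
loglikKernel <- function(data, gamma, params) {
  stopifnot(is(data, "GeneSummaryData"), is(params, "ModelParams"))
  gamma <- as.numeric(gamma)
  m <- nSnps(data)
  if (length(gamma) != m) {
    stop("gamma has length ", length(gamma), " but data has ", m, " SNPs")
  }
  if (any(!is.finite(gamma))) stop("non-finite entries in gamma")
  a <- params@alpha_prime
  tau <- params@tau
  s2 <- params@sigma2_gamma
  tau * sum(data@eqtl_z * gamma) -
    tau^2 / 2 * sum(gamma * (data@ld_eqtl %*% gamma)) +
    a * sum(data@gwas_z * gamma) -
    a^2 / 2 * sum(gamma * (data@ld_gwas %*% gamma)) -
    sum(gamma^2) / (2 * s2) - m / 2 * log(2 * pi * s2)
}

# Joint covariance of c(eqtl_z, gwas_z) after integrating gamma out.
.marginal_cov <- function(data, params) {
  R1 <- data@ld_eqtl
  R2 <- data@ld_gwas
  s2 <- params@sigma2_gamma
  a <- params@alpha_prime
  tau <- params@tau
  rbind(
    cbind(R1 + tau^2 * s2 * (R1 %*% R1), tau * a * s2 * (R1 %*% R2)),
    cbind(tau * a * s2 * (R2 %*% R1), R2 + a^2 * s2 * (R2 %*% R2))
  )
}

#' Exact marginal log-likelihood of the observed z-scores
#'
#' The model is linear-Gaussian, so integrating the latent effects out gives
#' a zero-mean joint Gaussian for the stacked z-scores with blocks
#' `Cov(z1) = R1 + tau^2 s2 R1 R1`, `Cov(z2) = R2 + alpha'^2 s2 R2 R2`,
#' `Cov(z1, z2) = tau alpha' s2 R1 R2`. Used as an independent check on the
#' variational fit (the ELBO can never exceed it); the fit itself never calls
#' it because it requires dense solves with the LD matrices.
#'
#' @inheritParams loglikKernel
#' @param drop_constant if `TRUE`, subtract the same parameter-free constant
#'   that [loglikKernel()] drops (`-z1' R1^{-1} z1 / 2 - z2' R2^{-1} z2 / 2 -
#'   log|2 pi R1|/2 - log|2 pi R2|/2`), making the value directly comparable
#'   with the ELBO arithmetic.
#' @return a single number.
#' @export
exactMarginalLoglik <- function(data, params, drop_constant = FALSE) {
  stopifnot(is(data, "GeneSummaryData"), is(params, "ModelParams"))
  z <- c(data@eqtl_z, data@gwas_z)
  S <- .marginal_cov(data, params)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("marginal covariance is not positive definite; ",
         "increase the LD shrinkage")
  }
  val <- -0.5 * sum(backsolve(ch, z, transpose = TRUE)^2) -
    sum(log(diag(ch))) - length(z) / 2 * log(2 * pi)
  if (drop_constant) {
    val <- val - .dropped_constant(data)
  }
  val
}

# The gamma- and parameter-free constant excluded from loglikKernel and the
# ELBO: -z1' R1^{-1} z1 / 2 - z2' R2^{-1} z2 / 2 - log|2 pi R1|/2 - log|2 pi R2|/2.
.dropped_constant <- function(data) {
  qform <- function(z, R) {
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      stop("LD matrix is not positive definite; increase the shrinkage")
    }
    -0.5 * sum(backsolve(ch, z, transpose = TRUE)^2) -
      sum(log(diag(ch))) - length(z) / 2 * log(2 * pi)
  }
  qform(data@eqtl_z, data@ld_eqtl) + qform(data@gwas_z, data@ld_gwas)
}

# Constant-dropped exact marginal log-likelihood through the low-rank
# identity: with R = blockdiag(R1, R2) and C = rbind(tau R1, alpha R2), the
# joint covariance is R + sigma2 C C', so Woodbury and the determinant lemma
# reduce everything to the m x m matrix M = I + sigma2 (tau^2 R1 + alpha^2 R2)
# and u = tau z1 + alpha z2:
#   ll = sigma2/2 * u' M^{-1} u - log|M|/2   (+ the dropped constant).
# No LD matrix is ever inverted. Agrees with
# exactMarginalLoglik(..., drop_constant = TRUE); kept separate because this
# path is what the test statistic evaluates per gene.
.rss_marginal_dropped <- function(z1, z2, R1, R2, sigma2, alpha, tau = 1) {
  m <- length(z1)
  M <- diag(m) + sigma2 * (tau^2 * R1 + alpha^2 * R2)
  u <- tau * z1 + alpha * z2
  ch <- chol(M)
  0.5 * sigma2 * sum(backsolve(ch, u, transpose = TRUE)^2) -
    sum(log(diag(ch)))
}

#' Scale constant linking the tested coefficient to the expression-on-trait
#' effect
#'
#' When both studies' summary statistics come from simple linear regression,
#' `alpha' = alpha * c` with
#' `c = (sd_expression / sd_trait) * sqrt(n_gwas / n_eqtl)`. Because `c > 0`,
#' testing `alpha' = 0` is the same as testing `alpha = 0`; `c` only converts
#' the estimate back to the interpretable scale.
#'
#' @param scale a [GeneScale-class] object.
#' @return the positive constant `c`.
#' @examples
#' computeCj(GeneScale(2, 1, 100, 400))  # 4
#' @export
computeCj <- function(scale) {
  stopifnot(is(scale, "GeneScale"))
  (scale@sd_expression / scale@sd_trait) * sqrt(scale@n_gwas / scale@n_eqtl)
}
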