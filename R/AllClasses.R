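#' @import methods
#' @importFrom stats cor cov pchisq pnorm qnorm rnorm runif rbinom sd var median
#'   coef qchisq quantile lm setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib stwas, .registration = TRUE
NULL

# Smallest admissible prior variance for the per-SNP effects; keeps null fits
# for genes with no eQTL signal away from a degenerate sigma_gamma^2 = 0.
.SIGMA2_FLOOR <- 1e-8

# Median of the chi-squared distribution with one degree of freedom, the
# denominator of the genomic inflation factor.
.CHISQ1_MEDIAN <- 0.4549364

.check_square_corr <- function(R, what, tol = 1e-6) {
  if (!is.matrix(R) || !is.numeric(R)) {
    return(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(R) != ncol(R)) return(sprintf("%s must be square", what))
  if (any(!is.finite(R))) return(sprintf("%s has non-finite entries", what))
  if (max(abs(R - t(R))) > tol) return(sprintf("%s must be symmetric", what))
  if (max(abs(diag(R) - 1)) > tol) {
    return(sprintf("%s must have unit diagonal", what))
  }
  NULL
}

#' Per-gene summary-statistics bundle
#'
#' Holds everything the summary-level association test needs for one gene:
#' the vector of per-SNP eQTL z-scores, the vector of per-SNP GWAS z-scores,
#' and the two SNP correlation (LD) matrices estimated from reference panels
#' matching the eQTL and GWAS populations. All five components are indexed in
#' the same SNP order, the order of `snp_ids`.
#'
#' @slot gene_id single gene identifier.
#' @slot eqtl_z numeric vector of eQTL z-scores, one per SNP.
#' @slot gwas_z numeric vector of GWAS z-scores, one per SNP.
#' @slot ld_eqtl symmetric unit-diagonal SNP correlation matrix for the eQTL
#'   population.
#' @slot ld_gwas symmetric unit-diagonal SNP correlation matrix for the GWAS
#'   population.
#' @slot snp_ids character vector of SNP identifiers defining the common
#'   ordering.
#'
#' @seealso [GeneSummaryData()] for the constructor, [lrtTest()] for the test.
#' @export
setClass("GeneSummaryData",
  representation(
    gene_id = "character",
    eqtl_z  = "numeric",
    gwas_z  = "numeric",
    ld_eqtl = "matrix",
    ld_gwas = "matrix",
    snp_ids = "character"
  )
)

setValidity("GeneSummaryData", function(object) {
  m <- length(object@eqtl_z)
  if (m < 1L) return("need at least one SNP")
  if (length(object@gwas_z) != m) return("eqtl_z and gwas_z lengths differ")
  if (length(object@snp_ids) != m) return("snp_ids length differs from z-scores")
  if (any(!is.finite(object@eqtl_z))) return("non-finite eQTL z-scores")
  if (any(!is.finite(object@gwas_z))) return("non-finite GWAS z-scores")
  for (nm in c("ld_eqtl", "ld_gwas")) {
    R <- slot(object, nm)
    msg <- .check_square_corr(R, nm)
    if (!is.null(msg)) return(msg)
    if (nrow(R) != m) return(sprintf("%s dimension differs from z-scores", nm))
  }
  TRUE
})

#' Construct a per-gene summary-statistics bundle
#'
#' @param gene_id gene identifier.
#' @param eqtl_z,gwas_z numeric vectors of per-SNP z-scores (same length,
#'   same SNP order).
#' @param ld_eqtl,ld_gwas SNP correlation matrices in the same SNP order,
#'   typically from [estimateLD()].
#' @param snp_ids SNP identifiers; defaults to `snp1 ... snpm`.
#' @return a [GeneSummaryData-class] object.
#' @examples
#' d <- GeneSummaryData("g1", eqtl_z = c(2, 1), gwas_z = c(0.5, 0.2),
#'                      ld_eqtl = diag(2), ld_gwas = diag(2))
#' nSnps(d)
#' @export
GeneSummaryData <- function(gene_id, eqtl_z, gwas_z, ld_eqtl, ld_gwas,
                            snp_ids = paste0("snp", seq_along(eqtl_z))) {
  new("GeneSummaryData",
      gene_id = as.character(gene_id),
      eqtl_z = as.numeric(eqtl_z), gwas_z = as.numeric(gwas_z),
      ld_eqtl = as.matrix(ld_eqtl), ld_gwas = as.matrix(ld_gwas),
      snp_ids = as.character(snp_ids))
}

#' Study-scale information for mapping the tested coefficient back to the
#' expression-on-trait scale
#'
#' The association test works on a rescaled coefficient `alpha' = alpha * c`
#' where `c = (sd_expression / sd_trait) * sqrt(n_gwas / n_eqtl)` when both
#' sets of summary statistics come from simple linear regression. `c` is a
#' positive constant, so the test itself never needs it; it is used only to
#' report `alpha` on the interpretable scale.
#'
#' @slot sd_expression sample standard deviation of the gene's expression.
#' @slot sd_trait sample standard deviation of the trait.
#' @slot n_eqtl eQTL study sample size.
#' @slot n_gwas GWAS sample size.
#' @seealso [computeCj()]
#' @export
setClass("GeneScale",
  representation(
    sd_expression = "numeric",
    sd_trait = "numeric",
    n_eqtl = "numeric",
    n_gwas = "numeric"
  )
)

setValidity("GeneScale", function(object) {
  v <- c(object@sd_expression, object@sd_trait, object@n_eqtl, object@n_gwas)
  if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0)) {
    return("all GeneScale fields must be single positive finite numbers")
  }
  TRUE
})

#' @rdname GeneScale-class
#' @param sd_expression,sd_trait,n_eqtl,n_gwas see slots.
#' @return a [GeneScale-class] object.
#' @export
GeneScale <- function(sd_expression, sd_trait, n_eqtl, n_gwas) {
  new("GeneScale", sd_expression = as.numeric(sd_expression),
      sd_trait = as.numeric(sd_trait), n_eqtl = as.numeric(n_eqtl),
      n_gwas = as.numeric(n_gwas))
}

#' Model parameters of the summary-statistics likelihood
#'
#' `sigma2_gamma` is the prior variance of the standardized per-SNP effects,
#' `alpha_prime` the rescaled expression-on-trait coefficient under test, and
#' `tau` the redundant expansion parameter multiplying the eQTL mean; the
#' reduced (original) model has `tau = 1`. When `null_model` is `TRUE` the
#' coefficient is pinned at zero.
#'
#' @slot sigma2_gamma positive prior variance (floored at 1e-8).
#' @slot alpha_prime real coefficient under test.
#' @slot tau expansion parameter.
#' @slot null_model logical; `TRUE` fixes `alpha_prime = 0`.
#' @export
setClass("ModelParams",
  representation(
    sigma2_gamma = "numeric",
    alpha_prime = "numeric",
    tau = "numeric",
    null_model = "logical"
  )
)

setValidity("ModelParams", function(object) {
  if (length(object@sigma2_gamma) != 1L || !is.finite(object@sigma2_gamma) ||
      object@sigma2_gamma < .SIGMA2_FLOOR) {
    return(sprintf("sigma2_gamma must be a finite scalar >= %g", .SIGMA2_FLOOR))
  }
  if (length(object@alpha_prime) != 1L || !is.finite(object@alpha_prime)) {
    return("alpha_prime must be a finite scalar")
  }
  if (length(object@tau) != 1L || !is.finite(object@tau)) {
    return("tau must be a finite scalar")
  }
  if (isTRUE(object@null_model) && object@alpha_prime != 0) {
    return("null_model = TRUE requires alpha_prime = 0")
  }
  TRUE
})

#' @rdname ModelParams-class
#' @param sigma2_gamma,alpha_prime,tau,null_model see slots.
#' @return a [ModelParams-class] object; `sigma2_gamma` is floored at 1e-8.
#' @export
ModelParams <- function(sigma2_gamma = 0.01, alpha_prime = 0, tau = 1,
                        null_model = FALSE) {
  new("ModelParams",
      sigma2_gamma = max(as.numeric(sigma2_gamma), .SIGMA2_FLOOR),
      alpha_prime = if (isTRUE(null_model)) 0 else as.numeric(alpha_prime),
      tau = as.numeric(tau), null_model = isTRUE(null_model))
}

#' Mean-field variational posterior over the per-SNP effects
#'
#' A fully factorized Gaussian `q(gamma) = prod_k N(mu_k, s2_k)`.
#'
#' @slot mu posterior means.
#' @slot s2 strictly positive posterior variances.
#' @export
setClass("VariationalPosterior",
  representation(mu = "numeric", s2 = "numeric")
)

setValidity("VariationalPosterior", function(object) {
  if (length(object@mu) != length(object@s2)) {
    return("mu and s2 must have equal length")
  }
  if (length(object@mu) < 1L) return("posterior must have at least one factor")
  if (any(!is.finite(object@mu)) || any(!is.finite(object@s2))) {
    return("non-finite posterior parameters")
  }
  if (any(object@s2 <= 0)) return("posterior variances must be positive")
  TRUE
})

#' @rdname VariationalPosterior-class
#' @param mu,s2 see slots.
#' @return a [VariationalPosterior-class] object.
#' @export
VariationalPosterior <- function(mu, s2) {
  new("VariationalPosterior", mu = as.numeric(mu), s2 = as.numeric(s2))
}

#' Result of one variational fit
#'
#' @slot params converged [ModelParams-class], mapped back to the reduced
#'   parameterization (`tau = 1`).
#' @slot posterior converged [VariationalPosterior-class] (also mapped back).
#' @slot elbo final evidence lower bound, with parameter-free constants
#'   dropped.
#' @slot elbo_trace ELBO after every half-step (posterior update, parameter
#'   update), non-decreasing up to numerical slack.
#' @slot n_iter number of full iterations performed.
#' @slot converged whether the relative ELBO change fell below tolerance.
#' @export
setClass("FitResult",
  representation(
    params = "ModelParams",
    posterior = "VariationalPosterior",
    elbo = "numeric",
    elbo_trace = "numeric",
    n_iter = "integer",
    converged = "logical"
  )
)

#' Per-gene association test result
#'
#' @slot gene_id gene identifier.
#' @slot lrt_stat likelihood-ratio statistic (clamped at zero).
#' @slot p_value upper-tail probability under chi-squared with 1 df.
#' @slot alpha_prime_hat estimated rescaled coefficient.
#' @slot alpha_hat estimate on the expression-on-trait scale, `NA` when no
#'   [GeneScale-class] was supplied.
#' @slot sigma2_hat estimated prior effect variance (alternative fit).
#' @slot n_snps number of SNPs used.
#' @slot clamped whether a negative raw statistic was clamped to zero.
#' @slot fit_null,fit_alt the two [FitResult-class] objects (empty for
#'   two-stage comparators, which have no variational fit).
#' @slot method label of the producing method (`"comm_s4"`, `"comm_s2"`,
#'   `"ridge"`, `"enet"`).
#' @export
setClass("TestResult",
  representation(
    gene_id = "character",
    lrt_stat = "numeric",
    p_value = "numeric",
    alpha_prime_hat = "numeric",
    alpha_hat = "numeric",
    sigma2_hat = "numeric",
    n_snps = "integer",
    clamped = "logical",
    fit_null = "FitResult",
    fit_alt = "FitResult",
    method = "character"
  )
)

setValidity("TestResult", function(object) {
  if (length(object@lrt_stat) != 1L || object@lrt_stat < 0) {
    return("lrt_stat must be a single non-negative number")
  }
  if (object@p_value < 0 || object@p_value > 1) return("p_value outside [0,1]")
  TRUE
})

#' Reference-panel genotypes for one gene's cis window
#'
#' Dosage matrix (samples by SNPs, values in \[0, 2\]) with SNP identifiers
#' and the allele pair each dosage counts (`a1` is the counted allele).
#'
#' @slot genotypes numeric matrix, samples in rows, SNPs in columns.
#' @slot snp_ids SNP identifiers (column order).
#' @slot a1 counted (effect) allele per SNP.
#' @slot a2 other allele per SNP.
#' @export
setClass("GenotypePanel",
  representation(
    genotypes = "matrix",
    snp_ids = "character",
    a1 = "character",
    a2 = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  G <- object@genotypes
  m <- ncol(G)
  if (nrow(G) < 2L) return("panel needs at least 2 samples")
  if (m < 1L) return("panel needs at least 1 SNP")
  if (any(!is.finite(G)) || any(G < 0) || any(G > 2)) {
    return("dosages must lie in [0, 2]")
  }
  if (length(object@snp_ids) != m) return("snp_ids length != number of SNPs")
  if (length(object@a1) != m || length(object@a2) != m) {
    return("allele vectors must match the number of SNPs")
  }
  TRUE
})

#' @rdname GenotypePanel-class
#' @param genotypes,snp_ids,a1,a2 see slots; alleles default to the
#'   placeholder pair A/B when the panel carries no allele information.
#' @return a [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(genotypes,
                          snp_ids = colnames(genotypes),
                          a1 = rep("A", ncol(genotypes)),
                          a2 = rep("B", ncol(genotypes))) {
  genotypes <- as.matrix(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  new("GenotypePanel", genotypes = genotypes,
      snp_ids = as.character(snp_ids),
      a1 = as.character(a1), a2 = as.character(a2))
}

#' Individual-level eQTL data paired with GWAS summary statistics
#'
#' Input for the individual-level-eQTL comparator test and for the two-stage
#' predict-then-associate comparators: raw expression and genotypes for the
#' eQTL samples, GWAS z-scores and a GWAS-population LD matrix for the same
#' SNPs, in the same order.
#'
#' @slot gene_id gene identifier.
#' @slot y expression vector (eQTL samples).
#' @slot genotypes eQTL genotype dosage matrix, samples by SNPs.
#' @slot gwas_z GWAS z-scores per SNP.
#' @slot ld_gwas GWAS-population SNP correlation matrix.
#' @slot panel_sd per-SNP genotype standard deviations from the GWAS
#'   reference panel (used by the two-stage statistic).
#' @slot snp_ids SNP identifiers.
#' @export
setClass("IndividualEqtlData",
  representation(
    gene_id = "character",
    y = "numeric",
    genotypes = "matrix",
    gwas_z = "numeric",
    ld_gwas = "matrix",
    panel_sd = "numeric",
    snp_ids = "character"
  )
)

setValidity("IndividualEqtlData", function(object) {
  m <- ncol(object@genotypes)
  if (length(object@y) != nrow(object@genotypes)) {
    return("length(y) must equal nrow(genotypes)")
  }
  if (length(object@gwas_z) != m) return("gwas_z length != number of SNPs")
  msg <- .check_square_corr(object@ld_gwas, "ld_gwas")
  if (!is.null(msg)) return(msg)
  if (nrow(object@ld_gwas) != m) return("ld_gwas dimension != number of SNPs")
  if (length(object@panel_sd) != m || any(object@panel_sd <= 0)) {
    return("panel_sd must be positive, one value per SNP")
  }
  v <- apply(object@genotypes, 2L, var)
  if (any(v == 0)) {
    return(sprintf("constant genotype column: %s",
                   object@snp_ids[which(v == 0)[1L]]))
  }
  TRUE
})

#' @rdname IndividualEqtlData-class
#' @param gene_id,y,genotypes,gwas_z,ld_gwas,panel_sd,snp_ids see slots;
#'   `panel_sd` defaults to the column standard deviations of `genotypes`.
#' @return an [IndividualEqtlData-class] object.
#' @export
IndividualEqtlData <- function(gene_id, y, genotypes, gwas_z, ld_gwas,
                               panel_sd = apply(as.matrix(genotypes), 2L, sd),
                               snp_ids = paste0("snp", seq_along(gwas_z))) {
  new("IndividualEqtlData", gene_id = as.character(gene_id),
      y = as.numeric(y), genotypes = as.matrix(genotypes),
      gwas_z = as.numeric(gwas_z), ld_gwas = as.matrix(ld_gwas),
      panel_sd = as.numeric(panel_sd), snp_ids = as.character(snp_ids))
}
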