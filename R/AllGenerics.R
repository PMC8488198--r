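# Accessor generics and show methods. Slot access from user code goes through
# these; the slot layout is not part of the package interface.

#' @name accessors
#' @title Accessors for stwas objects
#' @description Small accessor functions for the S4 containers:
#'   `geneId()`, `snpIds()`, `nSnps()`, `eqtlZ()`, `gwasZ()`, `ldEqtl()`,
#'   `ldGwas()`, `genotypes()`, `lrtStat()`, `pValue()`, `alphaPrimeHat()`,
#'   `alphaHat()`, `sigma2Hat()`, `elboFinal()`, `elboTrace()`,
#'   `isConverged()`, `posteriorMean()`, `posteriorVar()`, `fitParams()`.
#' @param x an stwas S4 object of the matching class.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("eqtlZ", function(x) standardGeneric("eqtlZ"))
#' @rdname accessors
#' @export
setGeneric("gwasZ", function(x) standardGeneric("gwasZ"))
#' @rdname accessors
#' @export
setGeneric("ldEqtl", function(x) standardGeneric("ldEqtl"))
#' @rdname accessors
#' @export
setGeneric("ldGwas", function(x) standardGeneric("ldGwas"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("lrtStat", function(x) standardGeneric("lrtStat"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("alphaPrimeHat", function(x) standardGeneric("alphaPrimeHat"))
#' @rdname accessors
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))
#' @rdname accessors
#' @export
setGeneric("sigma2Hat", function(x) standardGeneric("sigma2Hat"))
#' @rdname accessors
#' @export
setGeneric("elboFinal", function(x) standardGeneric("elboFinal"))
#' @rdname accessors
#' @export
setGeneric("elboTrace", function(x) standardGeneric("elboTrace"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setGeneric("posteriorVar", function(x) standardGeneric("posteriorVar"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname accessors
setMethod("geneId", "GeneSummaryData", function(x) x@gene_id)
#' @rdname accessors
setMethod("geneId", "TestResult", function(x) x@gene_id)
#' @rdname accessors
setMethod("geneId", "IndividualEqtlData", function(x) x@gene_id)
#' @rdname accessors
setMethod("snpIds", "GeneSummaryData", function(x) x@snp_ids)
#' @rdname accessors
setMethod("snpIds", "GenotypePanel", function(x) x@snp_ids)
#' @rdname accessors
setMethod("nSnps", "GeneSummaryData", function(x) length(x@eqtl_z))
#' @rdname accessors
setMethod("nSnps", "GenotypePanel", function(x) ncol(x@genotypes))
#' @rdname accessors
setMethod("nSnps", "TestResult", function(x) x@n_snps)
#' @rdname accessors
setMethod("eqtlZ", "GeneSummaryData", function(x) x@eqtl_z)
#' @rdname accessors
setMethod("gwasZ", "GeneSummaryData", function(x) x@gwas_z)
#' @rdname accessors
setMethod("gwasZ", "IndividualEqtlData", function(x) x@gwas_z)
#' @rdname accessors
setMethod("ldEqtl", "GeneSummaryData", function(x) x@ld_eqtl)
#' @rdname accessors
setMethod("ldGwas", "GeneSummaryData", function(x) x@ld_gwas)
#' @rdname accessors
setMethod("ldGwas", "IndividualEqtlData", function(x) x@ld_gwas)
#' @rdname accessors
setMethod("genotypes", "GenotypePanel", function(x) x@genotypes)
#' @rdname accessors
setMethod("genotypes", "IndividualEqtlData", function(x) x@genotypes)
#' @rdname accessors
setMethod("lrtStat", "TestResult", function(x) x@lrt_stat)
#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@p_value)
#' @rdname accessors
setMethod("alphaPrimeHat", "TestResult", function(x) x@alpha_prime_hat)
#' @rdname accessors
setMethod("alphaHat", "TestResult", function(x) x@alpha_hat)
#' @rdname accessors
setMethod("sigma2Hat", "TestResult", function(x) x@sigma2_hat)
#' @rdname accessors
setMethod("elboFinal", "FitResult", function(x) x@elbo)
#' @rdname accessors
setMethod("elboTrace", "FitResult", function(x) x@elbo_trace)
#' @rdname accessors
setMethod("isConverged", "FitResult", function(x) x@converged)
#' @rdname accessors
setMethod("posteriorMean", "FitResult", function(x) x@posterior@mu)
#' @rdname accessors
setMethod("posteriorMean", "VariationalPosterior", function(x) x@mu)
#' @rdname accessors
setMethod("posteriorVar", "FitResult", function(x) x@posterior@s2)
#' @rdname accessors
setMethod("posteriorVar", "VariationalPosterior", function(x) x@s2)
#' @rdname accessors
setMethod("fitParams", "FitResult", function(x) x@params)

setMethod("show", "GeneSummaryData", function(object) {
  cat(sprintf("GeneSummaryData: gene %s, %d SNPs\n",
              object@gene_id, length(object@eqtl_z)))
  cat(sprintf("  |eQTL z| max %.3f, |GWAS z| max %.3f\n",
              max(abs(object@eqtl_z)), max(abs(object@gwas_z))))
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    "ModelParams: sigma2_gamma=%.4g, alpha_prime=%.4g, tau=%.4g%s\n",
    object@sigma2_gamma, object@alpha_prime, object@tau,
    if (object@null_model) " (null model)" else ""))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: ELBO %.4f after %d iterations (%s)\n",
    object@elbo, object@n_iter,
    if (object@converged) "converged" else "not converged"))
  show(object@params)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf(
    "TestResult [%s]: gene %s, LRT=%.4f, p=%.3g, alpha'=%.4g\n",
    object@method, object@gene_id, object@lrt_stat, object@p_value,
    object@alpha_prime_hat))
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d samples x %d SNPs\n",
              nrow(object@genotypes), ncol(object@genotypes)))
})

setMethod("show", "IndividualEqtlData", function(object) {
  cat(sprintf("IndividualEqtlData: gene %s, %d samples x %d SNPs\n",
              object@gene_id, length(object@y), ncol(object@genotypes)))
})
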