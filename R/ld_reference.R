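# LD estimation from reference panels and four-way SNP/allele harmonization.

#' Shrunk SNP correlation matrix from a reference panel
#'
#' Computes the sample Pearson correlation `P` of the (mean-centered)
#' genotype columns and returns `R = (1 - s) P + s I`. Any `s > 0` makes `R`
#' strictly positive definite (its eigenvalues are at least `s`), which the
#' summary-statistics likelihood requires when the number of SNPs approaches
#' the panel size.
#'
#' @param panel a [GenotypePanel-class] or a numeric dosage matrix (samples
#'   by SNPs).
#' @param shrinkage shrinkage weight `s` in \[0, 1\]; default 0.1, sized for
#'   panels of a few hundred samples.
#' @return a symmetric unit-diagonal correlation matrix.
#' @examples
#' g <- matrix(rbinom(200, 2, 0.3), 50, 4)
#' R <- estimateLD(g, shrinkage = 0.1)
#' range(eigen(R, only.values = TRUE)$values)  # >= 0.1
#' @export
estimateLD <- function(panel, shrinkage = 0.1) {
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  G <- if (is(panel, "GenotypePanel")) panel@genotypes else as.matrix(panel)
  ids <- if (is(panel, "GenotypePanel")) panel@snp_ids else colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  v <- apply(G, 2L, var)
  if (any(v == 0)) {
    stop("zero-variance genotype column: ", ids[which(v == 0)[1L]])
  }
  P <- cor(G)
  R <- (1 - shrinkage) * P + shrinkage * diag(ncol(G))
  dimnames(R) <- list(ids, ids)
  R
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_ambiguous <- function(a1, a2) {
  u1 <- toupper(a1)
  u2 <- toupper(a2)
  ifelse(is.na(.COMPLEMENT[u1]), FALSE, .COMPLEMENT[u1] == u2)
}

# Orientation of (a1, a2) relative to reference alleles (r1, r2):
# +1 same counted allele, -1 swapped, NA unresolvable. Strand flips
# (complementary encodings) are tolerated for unambiguous SNPs.
.allele_orientation <- function(a1, a2, r1, r2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  r1 <- toupper(r1); r2 <- toupper(r2)
  c1 <- unname(.COMPLEMENT[a1])
  c2 <- unname(.COMPLEMENT[a2])
  out <- rep(NA_real_, length(a1))
  out[a1 == r1 & a2 == r2] <- 1
  out[a1 == r2 & a2 == r1] <- -1
  flip_same <- !is.na(c1) & !is.na(c2) & c1 == r1 & c2 == r2
  flip_swap <- !is.na(c1) & !is.na(c2) & c1 == r2 & c2 == r1
  out[is.na(out) & flip_same] <- 1
  out[is.na(out) & flip_swap] <- -1
  out
}

#' Harmonize eQTL statistics, GWAS statistics and two reference panels
#'
#' Intersects the SNPs present in all four sources, aligns every source to
#' the GWAS panel's effect-allele orientation (z-scores change sign, panel
#' dosages are reflected as `2 - g`, when the allele pair is swapped;
#' complementary-strand encodings of unambiguous SNPs are recognized), drops
#' strand-ambiguous (A/T, C/G) SNPs and SNPs whose allele pairs cannot be
#' reconciled (both with a message), estimates both LD matrices from the
#' aligned panels, and returns the assembled per-gene bundle. Output SNP
#' order is the GWAS panel's order restricted to the intersection. The
#' operation is idempotent: harmonizing already-harmonized inputs changes
#' nothing.
#'
#' @param eqtl_stats,gwas_stats data frames with columns `snp`, `a1`, `a2`,
#'   `z` (one row per SNP for one gene).
#' @param panel_eqtl,panel_gwas [GenotypePanel-class] objects.
#' @param shrinkage LD shrinkage passed to [estimateLD()].
#' @param gene_id identifier for the returned bundle.
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @return a [GeneSummaryData-class] object.
#' @export
harmonizeGene <- function(eqtl_stats, gwas_stats, panel_eqtl, panel_gwas,
                          shrinkage = 0.1, gene_id = "gene",
                          drop_ambiguous = TRUE) {
  for (df in list(eqtl_stats, gwas_stats)) {
    if (!all(c("snp", "a1", "a2", "z") %in% names(df))) {
      stop("summary-statistics tables need columns snp, a1, a2, z")
    }
  }
  stopifnot(is(panel_eqtl, "GenotypePanel"), is(panel_gwas, "GenotypePanel"))
  ref_ids <- panel_gwas@snp_ids
  keep <- ref_ids[ref_ids %in% eqtl_stats$snp & ref_ids %in% gwas_stats$snp &
                    ref_ids %in% panel_eqtl@snp_ids]
  if (length(keep) == 0L) stop("no SNPs shared by all four sources")

  ig <- match(keep, ref_ids)
  r1 <- panel_gwas@a1[ig]
  r2 <- panel_gwas@a2[ig]

  if (drop_ambiguous) {
    amb <- .is_ambiguous(r1, r2)
    if (any(amb)) {
      message(sprintf("dropping %d strand-ambiguous SNP(s)", sum(amb)))
      keep <- keep[!amb]
      if (length(keep) == 0L) stop("no SNPs left after ambiguity filter")
      ig <- match(keep, ref_ids)
      r1 <- panel_gwas@a1[ig]
      r2 <- panel_gwas@a2[ig]
    }
  }

  align <- function(a1, a2) .allele_orientation(a1, a2, r1, r2)

  ie <- match(keep, eqtl_stats$snp)
  iw <- match(keep, gwas_stats$snp)
  ip <- match(keep, panel_eqtl@snp_ids)
  flips <- cbind(
    eqtl = align(eqtl_stats$a1[ie], eqtl_stats$a2[ie]),
    gwas = align(gwas_stats$a1[iw], gwas_stats$a2[iw]),
    panel = align(panel_eqtl@a1[ip], panel_eqtl@a2[ip])
  )
  ok <- stats::complete.cases(flips)
  if (!all(ok)) {
    message(sprintf("dropping %d SNP(s) with unresolvable allele pairs",
                    sum(!ok)))
    keep <- keep[ok]
    if (length(keep) == 0L) stop("no SNPs left after allele reconciliation")
    ig <- match(keep, ref_ids); ie <- ie[ok]; iw <- iw[ok]; ip <- ip[ok]
    flips <- flips[ok, , drop = FALSE]
    r1 <- panel_gwas@a1[ig]; r2 <- panel_gwas@a2[ig]
  }

  G1 <- panel_eqtl@genotypes[, ip, drop = FALSE]
  swap1 <- flips[, "panel"] < 0
  if (any(swap1)) G1[, swap1] <- 2 - G1[, swap1]
  G2 <- panel_gwas@genotypes[, ig, drop = FALSE]

  GeneSummaryData(
    gene_id = gene_id,
    eqtl_z = eqtl_stats$z[ie] * flips[, "eqtl"],
    gwas_z = gwas_stats$z[iw] * flips[, "gwas"],
    ld_eqtl = estimateLD(GenotypePanel(G1, snp_ids = keep, a1 = r1, a2 = r2),
                         shrinkage = shrinkage),
    ld_gwas = estimateLD(GenotypePanel(G2, snp_ids = keep, a1 = r1, a2 = r2),
                         shrinkage = shrinkage),
    snp_ids = keep
  )
}
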