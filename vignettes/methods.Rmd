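---
title: "Testing expression-trait association from summary statistics: model, algorithm and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing expression-trait association from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwas)
```

## The problem

A transcriptome-wide association study (TWAS) asks, gene by gene, whether the
genetically regulated component of a gene's expression is associated with a
complex trait. Classical two-stage approaches train an expression predictor in
an eQTL cohort and then test the weighted GWAS signal; likelihood-based
approaches instead model both studies jointly, which propagates the
uncertainty of the expression model into the test. Both traditionally need
individual-level expression data. Large eQTL resources, however, release only
summary statistics. This package implements a likelihood-ratio TWAS that
needs nothing but per-SNP z-scores from the eQTL study, per-SNP z-scores from
the GWAS, and SNP correlation (LD) matrices estimated from reference panels
matched to the two populations.

## The model

For one gene with $m$ cis-SNPs, let $\hat\gamma_1, \hat\gamma_2 \in
\mathbb{R}^m$ be the eQTL and GWAS z-score vectors and $\hat R_1, \hat R_2$
the two LD matrices. Writing $\gamma$ for the latent standardized (z-score
scale) joint eQTL effects, the regression-with-summary-statistics
approximation gives

$$
\hat\gamma_1 \mid \gamma \sim N(\hat R_1 \gamma,\; \hat R_1), \qquad
\hat\gamma_2 \mid \gamma \sim N(\alpha' \hat R_2 \gamma,\; \hat R_2), \qquad
\gamma \sim N(0, \sigma_\gamma^2 I_m).
$$

Here $\alpha' = \alpha c$ is a rescaling of the expression-on-trait effect
$\alpha$; with simple-linear-regression summary statistics, $c =
(\hat\sigma_y / \hat\sigma_z)\sqrt{n_2 / n_1}$ (`computeCj()`), a positive
constant, so testing $\alpha' = 0$ and testing $\alpha = 0$ are the same
test. The per-gene null hypothesis is $H_0: \alpha' = 0$, assuming no
horizontal pleiotropy; in real data a rejection can also reflect pleiotropic
paths, a caveat shared by all TWAS-style tests.

All terms of the log-likelihood that depend on neither $\gamma$ nor the
parameters — the quadratic forms in $\hat R^{-1}$ and the log-determinants —
are dropped everywhere (`loglikKernel()`). They cancel exactly in the
likelihood-ratio statistic, and dropping them means the algorithm never
inverts an LD matrix, which is the point of the variational fit below.

## PX-VBEM

The parameters $\theta = \{\sigma_\gamma^2, \alpha'\}$ are estimated by
variational Bayes EM with a fully factorized Gaussian posterior
$q(\gamma) = \prod_k N(\mu_k, s_k^2)$. The E-step is a sequential
(Gauss–Seidel) sweep of the exact coordinate updates, in ascending SNP index
for determinism; the M-step sets each parameter to its closed-form ELBO
maximizer. Both half-steps increase the evidence lower bound, so the ELBO
trace is monotone — a property the test suite checks at every half-step.

Convergence is accelerated by parameter expansion: a redundant parameter
$\tau$ multiplies the eQTL mean, $\hat\gamma_1 \mid \gamma \sim N(\tau \hat
R_1 \gamma, \hat R_1)$, and is updated alongside the other parameters. We
expand only the eQTL arm — the expansion is stated for that arm and the GWAS
arm already carries its own free scale through $\alpha'$. After convergence
the fit is mapped back to the reduced model ($\tau = 1$) by
$\sigma_\gamma^2 \leftarrow \tau^2 \sigma_\gamma^2$,
$\alpha' \leftarrow \alpha' / \tau$ (and $\mu \leftarrow \tau\mu$,
$s^2 \leftarrow \tau^2 s^2$), which leaves the marginal likelihood and the
ELBO unchanged — verified numerically in the tests. On LD-correlated
instances the expansion typically cuts the iteration count severalfold at an
identical final ELBO.

Defaults: $\sigma_\gamma^2 = 0.01$, $\alpha' = 0$, $\tau = 1$, $\mu = 0$,
$s^2 = \sigma_\gamma^2$; convergence when the relative ELBO change drops
below $10^{-6}$, capped at 1000 iterations; $\sigma_\gamma^2$ floored at
$10^{-8}$ so genes with no eQTL signal cannot drive the null fit degenerate.

## The likelihood-ratio test

The statistic is $\Lambda = 2(\ell_{alt} - \ell_{null})$, referred to
$\chi^2_1$, where $\ell$ is the maximized marginal log-likelihood of each
hypothesis. Three deliberate choices:

* **The exact marginal, not the ELBO, is the tested surface.** The model is
  linear-Gaussian, so the marginal of the observed z-scores is a closed-form
  Gaussian; writing the joint covariance as $\mathrm{blockdiag}(\hat R_1,
  \hat R_2) + \sigma_\gamma^2 CC^\top$ with $C = (\tau \hat R_1; \alpha'
  \hat R_2)$, Woodbury and the matrix-determinant lemma collapse the
  constant-dropped log-likelihood to $\frac{\sigma_\gamma^2}{2} u^\top
  M^{-1} u - \frac12 \log |M|$ with $M = I_m + \sigma_\gamma^2 (\tau^2 \hat
  R_1 + \alpha'^2 \hat R_2)$ and $u = \tau\hat\gamma_1 + \alpha'
  \hat\gamma_2$ — pure $m \times m$ arithmetic, still no LD inversion. The
  test profiles this surface in the one or two free parameters, starting
  from the PX-VBEM solution (and, for the alternative, from the null
  optimum as well, which makes the nesting numerically airtight). We chose
  this over the ELBO difference after measuring both: the mean-field bound
  is systematically tighter under the null than under the alternative when
  LD is strong, which depresses $\Lambda$ and costs material power at weak
  cellular heritability, while the exact-marginal ratio holds the nominal
  size in the null simulations (both behaviors are measured by the test
  suite's power and calibration checks). The ELBO-difference statistic remains available
  (`statistic = "elbo"`); the dense-algebra `exactMarginalLoglik()` is the
  independent oracle the fast identity is tested against.
* **Warm start.** The alternative variational fit starts from the null
  fit's posterior and prior variance, which speeds it up and stabilizes the
  profiling starts.
* **Clamping.** A negative raw $\Lambda$ can arise only by numerical noise
  (the alternative search includes the null optimum); it is clamped at zero
  and the clamp is flagged on the result, leaving a (practically empty)
  atom at $p = 1$ that the calibration tests tolerate.

`genomicInflation()` reports $\lambda_{GC} = \mathrm{median}(\Lambda) /
0.4549364$, and `significantGenes()` applies the conventional fixed
transcriptome-wide cut $p < 5\times10^{-6}$ (Bonferroni available as an
option).

## LD estimation and harmonization

`estimateLD()` returns $(1-s)\,P + s I$ with $P$ the sample Pearson
correlation of the panel dosages. The shrinkage $s$ guarantees eigenvalues
$\ge s$; reference panels here are a few hundred samples against $m \approx
100$ SNPs, so some regularization is prudent. The default is $s = 0.1$ for
user-supplied panels and $s = 0.05$ inside the simulation suite; both are
exposed. No particular LD regularization is canonical for this model class —
the value is a package decision, not a fitted quantity.

`harmonizeGene()` intersects the SNPs of the four sources (eQTL stats, GWAS
stats, two panels), orients every source to the GWAS panel's effect allele —
flipping z-score signs and reflecting dosages $g \mapsto 2-g$ where the
allele pair is swapped, recognizing complementary-strand encodings — and
drops strand-ambiguous (A/T, C/G) SNPs. Output order is the GWAS panel
order; the operation is idempotent.

## What the simulator emulates

`buildWorld()` generates the linked two-study design used throughout the
power and calibration experiments:

* **Genotypes** (`simulateGenotypes()`): each sample's latent row is a
  stationary AR-1 Gaussian across SNP positions with adjacent correlation
  $\rho \in \{0.2, 0.5, 0.8\}$, thresholded at the Hardy–Weinberg quantiles
  of a per-SNP MAF drawn from $U(0.05, 0.5)$. AR-1 is our reading of "an LD
  structure parameterized by $\rho$": it is the standard choice in this
  literature and makes adjacent-SNP latent correlation equal $\rho$ exactly.
* **Expression**: $y = W_1\gamma + e_1$ with spike-and-slab $\gamma$
  (inclusion probability = sparsity $\pi$, slab $N(0,1)$, all-zero draws
  rejected). The noise variance is set from the *realized* genetic variance
  so the cellular heritability $h_C^2$ holds exactly per replicate rather
  than in expectation — exact finite-sample control was preferred over
  theoretical-variance calibration.
* **Trait**: $z = \alpha W_2\gamma + e_2$ with unit noise and $\alpha$
  scaled to the target trait heritability $h_T^2$ the same way; $h_T^2 = 0$
  is the null.
* **Summary statistics**: per-SNP simple linear regressions with $n-2$
  degrees of freedom, on both sides; LD matrices are estimated from separate
  finite panels ($n_3 = n_4 = 400$), so the test sees estimation noise in
  $\hat R$ exactly as it would in practice.

Scenario knobs: `shared` draws all four genotype matrices from one law;
`distinct_ld` gives the GWAS side its own MAFs and its own $\rho$ (default
0.8 against the eQTL side's 0.5 — the scenario is stated qualitatively in
the literature, the particular pair is our configurable default);
`distinct_ld_and_architecture` additionally retains only `overlap_fraction`
(default 0.5, also configurable) of the eQTL causal set on the GWAS side,
replacing the remainder with fresh causal SNPs from the same slab.

What the simulator does **not** emulate: realistic block-structured LD from
real haplotypes, allele-frequency/effect-size coupling, confounding and
population stratification, case–control ascertainment, or horizontal
pleiotropy. Passing the simulation suite therefore demonstrates internal
correctness and calibration under the stated generative model, not
robustness to the failure modes of real cohorts.

## The experiment harnesses

`powerExperiment()` sweeps the $h_C^2 \times \pi \times h_T^2$ grid,
rejecting at `alpha_level` (default 0.05 — the nominal level of the power
study is a parameter precisely because no single value is canonical), with
failures counted as non-rejections. `concordanceExperiment()` runs the
summary-level test and the individual-level-eQTL comparator on identical
worlds at the concordance-study sizes ($n_1 = n_2 = 5000$) and regresses one
statistic on the other, pooling the heritability grid.

The comparators: `commS2Test()` replaces the eQTL arm with the exact
individual-level Gaussian likelihood $y \mid \gamma \sim N(\tau W_1 \hat S_1
\gamma, \sigma_e^2 I)$, where $\hat S_1$ holds the per-SNP marginal OLS
standard errors — this keeps the latent effects on the z-score scale so the
two likelihood-ratio statistics are directly comparable — and is fitted by
the same expanded coordinate ascent with $\sigma_e^2$ free.
`twoStageTwas()` is the predict-then-associate comparator: a
cross-validated glmnet fit (ridge, or elastic net with mixing 0.5; 5-fold
CV, our default since no single scheme is canonical) followed by the
weighted summary statistic $z = \sum_k w_k \sigma_k \hat\gamma_{2k} \big/
\sqrt{w^\top D \hat R_2 D w}$ with $D = \mathrm{diag}(\sigma_k)$ from the
GWAS reference panel.

## Problem sizes used by the checks

The packaged experiments run at the study's design points: power at
$n_1 = 500$, $n_2 = 10{,}000$, $n_3 = n_4 = 400$, $m = 100$, $\rho = 0.5$,
$h_C^2 = 0.01$, $h_T^2 = 0.003$, $\pi = 0.1$ with 500 replicates; null
calibration at $n_1 = n_2 = 5000$ pooling $h_C^2 \in \{0.01, \dots, 0.09\}$
at $\pi = 0.2$ with 2000 replicates; concordance at $n_1 = n_2 = 5000$,
$\pi = 0.2$, pooling the heritability grid, with 300 replicates — a
reduced-replicate rendering of the 2000-replicate design, enough to resolve
an $R^2$ threshold of 0.80 comfortably. The null-calibration sparsity and
the pooling choices are package decisions where the study design leaves the
cell unspecified.

## Numerical and degenerate-input conventions

Zero-variance genotype columns are refused by name everywhere (a constant
SNP has no defined z-score or correlation). A SNP that explains an outcome
perfectly has an infinite z-score; `summaryStats()` errors by default or
emits a $\pm 10^6$ sentinel on request. A vanishing M-step denominator keeps
the previous parameter value with a warning; $\tau = 0$ at reduction time
returns the floored prior variance and flags degeneracy. Ties in the
coordinate sweep cannot occur (the update is a deterministic function of the
freshest means); all randomness in the simulation layer flows from explicit
seeds, and every generator is bitwise reproducible given (config, seed).

## Known limitations

The RSS approximation assumes the z-scores and the reference LD describe the
same population; panel mismatch inflates or deflates the statistic and is
not corrected. Mean-field variances are conservative under strong LD, so
$\hat\sigma_\gamma^2$ is slightly biased downward there (the test's
calibration is checked empirically, not inherited from theory). The model
fits one gene at a time — no conditional analysis, fine-mapping, score-type
test, or pleiotropy-robust variant is provided. PLINK/VCF-native input is
out of scope; genotypes arrive as delimited dosage matrices or pre-computed
correlation matrices.
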