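# stwas — transcriptome-wide association tests from summary statistics

`stwas` tests, gene by gene, whether the genetically regulated component of a
gene's expression is associated with a complex trait, using **only summary
statistics**: per-SNP z-scores from an eQTL study, per-SNP z-scores from a
GWAS, and SNP correlation (LD) matrices estimated from reference panels
matched to the two populations. It is aimed at statistical geneticists who
want a likelihood-based TWAS when individual-level expression data are
unavailable — the situation for the large eQTL meta-analytic resources —
together with a complete simulation harness for power and calibration
studies and re-implementations of the standard comparator methods.

## The model

For one gene with $m$ cis-SNPs, let $\hat\gamma_1, \hat\gamma_2$ be the eQTL
and GWAS z-score vectors and $\hat R_1, \hat R_2$ the LD matrices. With
$\gamma$ the latent standardized joint eQTL effects, the
regression-with-summary-statistics approximation gives

$$
\hat\gamma_1 \mid \gamma \sim N(\hat R_1\gamma, \hat R_1),\quad
\hat\gamma_2 \mid \gamma \sim N(\alpha' \hat R_2\gamma, \hat R_2),\quad
\gamma \sim N(0, \sigma_\gamma^2 I_m),
$$

where $\alpha' = \alpha c$ rescales the expression-on-trait effect $\alpha$
by a known positive constant
$c = (\hat\sigma_y/\hat\sigma_z)\sqrt{n_2/n_1}$. The per-gene test is the
likelihood-ratio test of $H_0\colon \alpha' = 0$ (equivalently $\alpha = 0$,
assuming no horizontal pleiotropy), referred to $\chi^2_1$. Parameters are
fitted by a parameter-expanded variational Bayes EM algorithm (mean-field
Gaussian posterior, monotone ELBO, expansion parameter $\tau$ on the eQTL
arm for acceleration); the statistic itself profiles the exact closed-form
Gaussian marginal — collapsed to $m\times m$ arithmetic by a Woodbury
identity, so no LD matrix is ever inverted. See the methods vignette
(`vignettes/methods.Rmd`) for the full account.

## Worked example

Simulate one gene's linked eQTL/GWAS world at the default study design
(eQTL $n_1 = 500$, GWAS $n_2 = 10{,}000$, panels of 400, $m = 100$ cis-SNPs,
AR-1 LD with $\rho = 0.5$, cellular heritability 0.05, trait heritability
0.003) and test it:

```r
library(stwas)
cfg <- scenarioConfig(n_eqtl = 500, n_gwas = 10000, m = 100, rho = 0.5,
                      sparsity = 0.1, h_cell = 0.05, h_trait = 0.003)
world <- buildWorld(cfg, rep_seed = 1)
world$summary
#> GeneSummaryData: gene sim_seed1, 100 SNPs
#>   |eQTL z| max 3.227, |GWAS z| max 3.715

res <- lrtTest(world$summary, scale = world$scale)
res
#> TestResult [comm_s4]: gene sim_seed1, LRT=3.9145, p=0.0479, alpha'=1.392

resultsTable(res)
#>        gene m_snps alpha_prime_hat sigma2_hat      lrt     pvalue
#> 1 sim_seed1    100        1.392227 0.09547321 3.914535 0.04787025
#>   converged_null converged_alt clamped  method
#> 1           TRUE          TRUE   FALSE comm_s4
```

The likelihood-ratio statistic 3.91 exceeds the $\chi^2_1$ 95th percentile
(3.84), so this weakly heritable gene is (just) detected at level 0.05:
`pvalue` is the $\chi^2_1$ upper-tail probability, `alpha_prime_hat` the
fitted rescaled effect, and `sigma2_hat` the fitted prior variance of the
per-SNP effects. For real data, build the per-gene input with
`readSummaryStats()` + `readGenotypePanel()` + `harmonizeGene()` (which
intersects SNPs, aligns effect alleles and estimates shrunk LD), run batches
with `runGenes()`, and summarize with `genomicInflation()` /
`significantGenes()`. A thin command-line wrapper with `test`, `simulate`,
`power`, `concordance` and `ld` subcommands is installed at
`inst/scripts/stwas`.

Comparators for method studies: `commS2Test()` (same latent model, but the
eQTL arm uses individual-level expression) and `twoStageTwas()`
(cross-validated ridge / elastic-net predictor followed by the weighted
summary-statistic z-test).

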