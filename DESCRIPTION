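Package: stwas
Title: Transcriptome-Wide Association Tests from Summary-Level eQTL and
    GWAS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Probabilistic transcriptome-wide association testing using only
    summary statistics. Combines per-gene eQTL z-scores, GWAS z-scores and
    SNP correlation (LD) matrices from reference panels in a joint
    regression-with-summary-statistics likelihood, fits it by a
    parameter-expanded variational Bayes EM algorithm, and tests
    expression-trait association with a likelihood ratio test against a
    chi-squared reference with one degree of freedom. Includes a genotype and
    phenotype simulator for power and type-I-error studies, an
    individual-level-eQTL likelihood-ratio comparator, and two-stage
    predict-then-associate (ridge and elastic net) comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
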