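Package: gestgwas
Title: Fetal GWAS Toolkit for Gestational Duration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for fetal genome-wide association studies of
    gestational duration: simulation of mother-child duo cohorts with known
    fetal and maternal genetic architecture, rank-based inverse normal
    phenotype transformation, stratified single-SNP association testing,
    genomic control, SNP-level quality filters, fixed-effects inverse-variance
    meta-analysis with heterogeneity statistics, closed-form partitioning of
    fetal versus maternal genetic effects (conditional duo regression and the
    weighted linear model adjustment), a semi-parametric residual-bootstrap
    test for duration-dependent SNP effects, and simulation-based power for
    quantitative and case-control designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
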