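Package: sparsegwa
Title: Linear Mixed Model and Bayesian Sparse Linear Mixed Model
    Association Mapping with Candidate Pathway Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association tools for quantitative traits in
    inbred mapping panels: per-SNP linear mixed model (LMM) scans with a
    kinship random effect, principal-component structure covariates and
    Gao-corrected significance thresholds; a Bayesian sparse linear mixed
    model (BSLMM) fitted by Markov chain Monte Carlo that partitions trait
    variance into sparse (major-effect) and polygenic components and
    reports posterior inclusion probabilities, |beta x gamma| sparse
    effects and highest-posterior-density intervals; candidate pathway
    association restricted to SNPs inside annotated enzyme genes; and a
    block-LD genotype/phenotype simulator with exact in-sample control of
    the variance explained, so every stage of the workflow can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    rtracklayer,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
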