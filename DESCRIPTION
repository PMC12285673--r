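Package: amygrs
Title: Construction and Validation of Non-APOE Genetic Risk Scores for
    Quantitative Amyloid Endophenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for building and validating a
    clumping-and-thresholding (C+T) genetic risk score for a quantitative
    brain-amyloid endophenotype from multi-cohort genotype data.  Covers
    per-variant and per-sample genotype quality control (call rate,
    Hardy-Weinberg exact test, minor allele frequency, PI_HAT relatedness),
    covariate-adjusted additive-model GWAS with genetic principal
    components, DerSimonian-Laird random-effects inverse-variance
    meta-analysis, refinement of candidate variants against an independent
    neuropathology cohort, greedy LD clumping with a p-value entry
    threshold, weighted score computation, and association testing of the
    score against quantitative, binary, and held-out outcomes.  A
    synthetic-cohort generator with LD-block genotype structure, planted
    causal variants, ancestry strata and covariate effects makes the whole
    pipeline testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
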