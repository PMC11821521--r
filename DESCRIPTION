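Package: slabgwas
Title: Spike-and-Slab Variational Whole-Genome Regression for Mixed-Model Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step mixed-model genome-wide association testing for
    quantitative and binary traits. Step one fits a Bayesian whole-genome
    regression with a spike-and-slab prior on variant effects by stochastic
    variational inference (with local reparameterization and antithetic
    variates), setting the prior from randomized Haseman-Elston variance
    components (quantitative) or a heritability grid search (binary), and
    produces leave-one-chromosome-out residual phenotypes. Step two computes
    proportional score statistics calibrated to an effective sample size,
    with an approximate Firth penalized-likelihood fallback for rare binary
    outcomes and an optional inverse-participation-weighted test with
    Huber-White variance. Includes PLINK bed/bim/fam input and output and a
    genotype/trait simulator with population stratification, close
    relatives, MAF-dependent architectures and liability-threshold binary
    traits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
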