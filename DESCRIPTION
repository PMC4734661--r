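Package: farmscan
Title: Iterative Fixed and Random Effect Model Genome-Wide Association Scans
Version: 0.1.0
Authors@R: person("farmscan", "developers", role = c("aut", "cre"),
    email = "maintainer@farmscan.dev")
Description: Multi-locus genome-wide association testing by iterating a
    fixed-effect single-marker scan (with pseudo-QTN covariates) against a
    random-effect REML model whose kinship is derived from the pseudo QTNs
    (the FarmCPU algorithm). Includes bin-based pseudo-QTN selection with
    restricted-likelihood optimization, P-value substitution, a phenotype
    simulator with geometric QTN effect sizes and target heritability, and
    power/FDR/Type-I-error/enrichment evaluation machinery, plus a small
    command-line interface for delimited genotype, map, phenotype and
    covariate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
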