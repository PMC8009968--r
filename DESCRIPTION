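Package: omnitrait
Title: Omnibus Multi-Phenotype Association Tests from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint association tests for a single genetic variant and multiple
    correlated phenotypes using only per-trait genome-wide association study
    (GWAS) summary statistics. Implements the generalized higher criticism
    (GHC) and generalized Berk-Jones (GBJ) supremum tests with analytic
    p-values obtained from an extended beta-binomial approximation to the
    boundary-crossing probability of the ordered absolute Z-scores, a
    correlation-aware minimum-p (MinP) test based on multivariate normal
    rectangle probabilities, and a Cauchy-combination omnibus (OMNI) test that
    aggregates the three. Includes harmonization of per-trait summary files,
    estimation of the between-trait correlation matrix from independent SNPs,
    a type-I error and power simulation suite, and a genome-scan command-line
    interface with genomic-inflation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    data.table,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
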