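Package: cophylotrace
Title: Cophylogenetic Signal Tests and Transfer-Rate Estimation for
    Host-Symbiont Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing codiversification between hosts and their
    symbionts from phylogenetic trees and host-symbiont association tables.
    Implements three congruence statistics with permutation significance
    tests (Procrustean superimposition of principal-coordinate embeddings,
    the information-based generalized Robinson-Foulds distance, and the Nye
    branch-alignment similarity), host-tip splitting so that tree distances
    accept several symbionts per host, extraction of habitat-specific clades
    from environment-annotated marker-gene trees with contig-based matching
    across markers, and horizontal-transfer rate estimation by
    duplication-transfer-loss reconciliation under an undated probabilistic
    model, judged against a no-transfer baseline built from replicate gene
    trees that share one true history. A host-symbiont cophylogeny simulator
    with codivergence, duplication, loss, host switching, incomplete
    sampling and reconstruction noise supports calibration and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    ape (>= 5.0),
    phangorn,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
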