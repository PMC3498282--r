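Package: bdltest
Title: Birth-Death Likelihood Models, Lineage-Through-Time Curves, and
    Rate-Constancy Testing for Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diversification-rate analysis on dated ultrametric
    phylogenies: extraction of branching times and lineage-through-time
    (LTT) series, maximum-likelihood fitting of five birth-death
    diversification models (pure birth, constant-rate birth-death,
    density-dependent logistic and exponential, and a two-rate pure-birth
    shift model), AIC-based model comparison under two conventions, a
    rate-constancy test statistic with a simulated pure-birth null
    distribution, pairwise uncorrected and HKY85 maximum-likelihood
    distances with group summaries, a global molecular-clock likelihood
    ratio test, and seeded generators for synthetic trees and alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
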