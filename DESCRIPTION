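Package: phylodisc
Title: Dissecting Gene-Tree Discordance into Lineage Sorting and Introgression
Version: 0.1.0
Authors@R: person("Phylodisc", "Developers", role = c("aut", "cre"),
    email = "maintainer@phylodisc.org")
Description: Tools to separate incomplete lineage sorting from ancient
    introgression in collections of gene trees and site patterns: a
    multispecies-coalescent simulator with discrete introgression pulses and
    clade rate multipliers, rooted-topology spectra, quartet concordance
    factors and polytomy tests, ABBA-BABA D-statistics with block-jackknife
    standard errors, exponential mixture tests on triplet internal branch
    lengths, local molecular clock model comparison by AICc and likelihood
    ratio tests, and Robinson-Foulds tree-space embedding by principal
    coordinates analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
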