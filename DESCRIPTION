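Package: plasmidfate
Title: Plasmid Decay Kinetics, Spread Potential, and Transconjugant
    Community Analysis for Composting Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fate of a plasmid-bearing donor strain
    and a conjugative multidrug-resistance plasmid during manure composting.
    Implements log-linear and biphasic decay fits with decimal reduction times
    (D-values) from droplet digital PCR (ddPCR) marker-gene time series, the
    spread-potential statistic (transconjugants per recipient) from gfp, dsRed
    and 16S rRNA gene concentrations, and community analysis of FACS-sorted
    transconjugant pools: alpha diversity (Sobs, Chao1, ACE, Shannon, Simpson,
    Good's coverage), Bray-Curtis dissimilarity, principal coordinate analysis,
    permutational multivariate analysis of variance, taxonomic aggregation and
    host-range set summaries. A synthetic-data generator simulates composting
    experiments with known ground truth (piecewise log-linear decay, Poisson
    droplet-occupancy ddPCR counting, Dirichlet-multinomial transconjugant
    communities) so every estimator can be checked against a recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
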