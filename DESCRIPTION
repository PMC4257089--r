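Package: tcellsim
Title: Stochastic Simulation of Logical Models of CD4+ T-Cell Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, exchanging and stochastically simulating
    Boolean logical models of cell signaling under continuous environmental
    activity levels, with an emphasis on CD4+ T-cell receptor and caveolin-1
    (CAV1) signaling. Provides a rule grammar and SBML-qual import/export,
    a semi-synchronous simulation engine with per-iteration Bernoulli
    resampling of external stimuli, genotype perturbations (knockout,
    forced activation), an exact Markov-chain oracle for small networks,
    in-silico knockout screens with most-affected-protein ranking,
    dose-response validation curves, and a downstream expression analysis
    pipeline (fold-change, uncentered-correlation average-linkage
    clustering with Cluster 3.0 compatible output, and Pearson correlation
    against a reference gene). Ships a curated reference CD4+ T-cell model
    and generators for random networks and synthetic fold-change data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
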