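Package: sirswitch
Title: Hysteresis and Bifurcation Analysis of Yeast Telomeric SIR Silencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying bistability and hysteresis in budding-yeast
    telomeric SIR silencing. Provides a stochastic nucleosome-lattice
    simulator of Sir-complex spreading with fixed Sir supply (titration)
    and inhibitor scaling, driven by the Gillespie algorithm; an in-silico
    hysteresis protocol with a statistical classifier that distinguishes a
    discontinuous (saddle-node-like) loss of the silenced state from a
    continuous (supercritical-pitchfork-like) merge; analysis pipelines for
    the two classic population assays, 5-FOA survival fractions from
    dilution plate counts and ADE2 colony-pigmentation Gaussian-mixture
    analysis; and seeded synthetic-data generators that emulate both assays
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
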