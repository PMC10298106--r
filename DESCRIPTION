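Package: synkin
Title: Kinetic Modelling of Synaptic Protein-DNA Complex Lifetimes from
    Single-Molecule Dwell Times
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stability of synaptic protein-DNA
    complexes (a protein bridging two DNA duplexes, such as the restriction
    enzyme SfiI) from single-molecule fluorescence dwell-time data. Implements
    a mean first-passage-time (MFPT) model of the two-step dissociation
    scheme state 2 <-> state 1 -> state 0 with entropic rebinding multiplicity
    m = L - f + 1 for an L-bp duplex and an f-bp protein footprint, exact
    Gillespie-style stochastic simulation of the scheme, generation of
    synthetic TIRF-like intensity traces, threshold-based fluorescence burst
    detection, survival-probability analysis with single-exponential fits and
    two-sample Kolmogorov-Smirnov comparisons, inversion of the lifetime
    equations to recover bond parameters and energies, and a config-driven
    end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
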