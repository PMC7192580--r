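Package: dascr
Title: Disassembly Asymmetry Score Classification of Clathrin Coat Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies fluorescence intensity trajectories of clathrin-coated
    structures from single-channel live-cell imaging into abortive coats,
    bona fide clathrin-coated pits and outlier traces. Traces are quantized
    into integer intensity states, a time-resolved disassembly risk function
    is estimated from forward and reverse transition probabilities of a
    control population, and three per-trace summary features of the
    projected risk series feed a k-medoids classifier. Downstream tooling
    covers stage-resolved endocytosis metrics with bootstrap confidence
    bands, normalized two-dimensional feature densities and difference maps,
    cross-day pooling with bootstrap phenotype statistics and permutation
    robustness tests, and a ratiometric epifluorescence/TIRF invagination
    depth estimator. A labeled synthetic trace simulator makes the full
    pipeline testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
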