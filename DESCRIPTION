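Package: causalem
Title: Causal Strength Measures and Causal Emergence for Discrete Markov Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A unified toolkit for quantifying causal strength in finite
    Markovian systems specified by transition probability matrices. Implements
    the causal primitives (sufficiency, necessity, determinism and degeneracy
    coefficients), a catalogue of twelve classical measures of causation
    (Galton/covariance, Eells, Suppes, Cheng, Good, Lewis, Pearl's PN/PS/PNS,
    closest-possible-world Lewis, bit-flip perturbation, effect information and
    effective information), and three families of intervention distributions
    (maximum-entropy, observational/stationary, and local Hamming-ball
    interventions). Provides coarse-graining of micro-level transition models
    onto macrostates and the causal-emergence statistic CE = CS_macro -
    CS_micro, together with rule-based generators for a determinism/degeneracy
    parameterized bipartite Markov chain and a noisy NAND Boolean network, and
    parameter-sweep tables for mapping emergence across noise regimes.
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
    withr,
    optparse
Config/testthat/edition: 3
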