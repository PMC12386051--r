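# causalem

Causal strength measures and causal emergence for discrete Markovian
systems.

## The problem

Many quantitative sciences need to say *how strong* a causal relationship
is — a gene knockout that mostly silences a pathway, a stimulation protocol
that usually triggers a response, a regulatory motif that reliably flips a
switch. Over the last century more than a dozen measures of causal strength
have been proposed in philosophy, psychology, statistics, and information
theory. When a system is modeled as a finite Markov chain whose transition
probability matrix (TPM) encodes `P(e | do(c))` for every pair of states,
all of these measures become computable from the same two *causal
primitives*:

- **sufficiency** `suff(e,c) = P(e|c)` — how reliably the cause produces
  the effect — and its information-theoretic extension, the **determinism**
  coefficient `det(c) = 1 − H(E|c)/log₂ n`;
- **necessity** `nec(e,c) = 1 − P(e|C\c)` — how irreplaceable the cause is
  — and its extension, the **degeneracy** coefficient
  `deg = 1 − H(E|C)/log₂ n`.

Here `P(e|C) = Σ_c P_C(c) P(e|c)` and `P(e|C\c)` is the same marginal with
the cause excluded and the remaining causes renormalized. The distribution
`P_C` over causes — the **intervention distribution** — encodes which
counterfactuals count: uniform (maximum entropy), the chain's stationary
distribution (observational), or a Hamming ball around the actual state
(local interventions).

`causalem` implements the primitives, twelve classical measures built from
them (Galton/covariance, Eells, Suppes, Cheng, Good, Lewis, Pearl's
PN/PS/PNS, closest-possible-world Lewis, bit-flip perturbation, effect
information, effective information), per-transition values and expectations,
and the **causal emergence** statistic

```
CE = CS_macro − CS_micro
```

comparing a measure's value on a coarse-grained macroscale TPM against the
underlying microscale. `CE > 0` (emergence) means the dimensionally reduced
description supports *stronger* causal relationships than the microscale it
supervenes on; `CE < 0` is causal reduction. Two rule-based model systems
are included for studying when emergence occurs: a bipartite Markov chain
whose determinism and degeneracy are tuned independently by a dilution and
a rewiring parameter while its two-state macroscale stays perfectly
deterministic, and a noisy NAND Boolean network.

## Worked example

```r
library(causalem)

micro <- bipartite_model(dilution = 0.3, rewiring = 0.5)   # 16 microstates
cg    <- bipartite_macro_mapping(micro)                    # A -> ON, B -> OFF

# a weak microscale transition, judged with local (Hamming-ball) interventions
causal_emergence("eells", micro, cg, "0000", "1110",
                 scope = "transition", intervention = "local", delta = 1)
#>   measure cause effect  cs_micro cs_macro       ce direction
#> 1   eells  0000   1110 -0.053125        1 1.053125 emergence
```

At the microscale, `0000 -> 1110` barely ever fires and its Eells score is
slightly negative (a weak *preventive* cause). Its macro image `ON -> OFF`
is deterministic and fully necessary, scoring 1: the coarse-grained
description carries more causal strength, `CE ≈ +1.05`.

```r
# effective information in expectation, maximum-entropy interventions
causal_emergence("effect_information", micro, cg,
                 scope = "expectation", intervention = "maxent",
                 weights = "intervention")
#>              measure       scope cs_micro cs_macro         ce direction
#> 1 effect_information expectation 1.251396        1 -0.2513959 reduction
```

For this parameterization the microscale's effective information
(1.25 bits) already beats the 1-bit macroscale: causal *reduction* — CE is
system-dependent, not automatic.

```r
# the primitives behind those numbers
pc <- local_distribution(micro$space, "0000", 1)
primitive_profile(micro, pc, "0000", "1111")
#>   cause effect  suff   nec nec_dagger det_transition det_state deg_effect
#> 1  0000   1111 0.388 0.859       0.19          0.658     0.329      0.401
#>   det_system deg_system
#> 1      0.329      0.109
```

Full parameter sweeps (`ce_sweep()`) tabulate CE for every measure over an
11 × 11 determinism-by-degeneracy lattice; `normalized_average_ce()`
combines them into a single emergence map. A thin command-line front end
(`inst/cli/causalem.R`, subcommands `generate | measures | emergence |
sweep`) drives the same functions from YAML/JSON configs, writing long-form
CSV tables; everything in the pipeline is deterministic, so identical
configs yield identical files.

## Documentation

The methods vignette (`vignettes/causal-emergence.Rmd`) derives the
primitives and measures, explains the intervention-distribution choices,
documents the model generators and every numerical convention (entropy
units, infinite and undefined values, periodic-chain stationary
distributions, cross-scale normalization of the bit-flip measure), and
states the limitations of the model systems.
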