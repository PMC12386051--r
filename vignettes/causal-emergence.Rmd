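---
title: "Measuring causal strength and causal emergence in Markovian systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring causal strength and causal emergence in Markovian systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalem)
```

## The modeling framework

`causalem` works on self-contained Markov chains over a finite state space
$\Omega$ of $n$ states. The system's causal structure is taken to be fully
specified by its transition probability matrix (TPM): entry $(c, e)$ is
$P(e \mid do(c))$, the probability of landing in state $e$ one step after
*intervening* to put the system in state $c$. Treating the TPM rows as
interventional rather than observational conditionals is the framework's
central assumption: the TPM is the causal model, and no hidden confounding
or exogenous noise variables are represented. Everything the package
computes — primitives, the twelve measures, causal emergence — is a
deterministic function of a TPM and an intervention distribution.

The **intervention distribution** $P_C$ is a probability vector over causes
that encodes which counterfactuals are considered and how they are
weighted. Three constructions are provided:

* `maxent_distribution()` — uniform $1/n$: every state intervened on
  equally, fully decoupled from the system's dynamics.
* `observational_distribution()` — the stationary distribution
  $\pi = \pi T$: counterfactuals are weighted by how often the system
  actually visits them.
* `local_distribution(space, center, delta)` — uniform on the Hamming ball
  $\{s : D_H(s, c^*) \le \Delta\}$ around the actual state: only "nearby
  possible worlds" are treated as viable interventions. This requires
  binary state labels, which supply the metric.

From a TPM and a $P_C$ the two probability kernels every measure consumes
are the marginal effect distribution
$P(e \mid C) = \sum_c P_C(c) P(e \mid c)$ and the counterfactual
distribution $P(e \mid C \setminus c)$, in which the excluded cause's mass
is renormalized over the remaining causes. Excluding a zero-mass cause is
the identity renormalization; excluding a cause holding *all* the mass is
an error (there is no counterfactual left to evaluate).

## Primitives and measures

Sufficiency $P(e|c)$ and necessity $1 - P(e|C\setminus c)$ are the
probabilistic primitives; the determinism and degeneracy coefficients are
their information-theoretic counterparts, normalized by $\log_2 n$ so that
both live in $[0,1]$ at state/system level. All entropies are in bits and
$0 \log_2 (1/0) \equiv 0$. The per-transition coefficients
$\mathrm{det}(e,c) = 1 - \log_2(1/P(e|c))/\log_2 n$ and
$\mathrm{deg}(e) = 1 - \log_2(1/P(e|C))/\log_2 n$ are $-\infty$ at zero
probability; they are returned as flagged infinite values rather than
errors so that expectations, which weight them by zero, stay computable.
The system-level coefficients skip zero-weight terms, which keeps them
finite and reproduces the identity
$\mathrm{det} = \sum_{c,e} P(c,e)\,\mathrm{det}(e,c)$ on full-support
systems.

The measure catalogue (`measure_catalogue()`) expresses each classical
measure through the primitives $s$, $v$, $m$ (sufficiency, necessity,
marginal): Eells $s+v-1$, Suppes $s-m$, Cheng $(s+v-1)/v$, Good
$\log_2(v/(1-s))$, Lewis $(s+v-1)/s$, Galton
$P_C(c)(1-P_C(c))(s+v-1)$, the effect information $\log_2(s/m)$, plus the
Hamming-based closest-possible-world Lewis and bit-flip measures and the
expectation-level effective information
$EI = \log_2 n\,(\mathrm{det}-\mathrm{deg})$ and effectiveness
$EI/\log_2 n$. Pearl's PNS, PN, and PS reduce exactly to Eells, Lewis, and
Cheng under the exogeneity and monotonicity assumptions already implicit in
reading the TPM as the full causal model; they are provided as aliases and
tested for bitwise equality. Only these simplified expressions are in
scope — general structural-model counterfactuals are not represented.

Sign conventions: negative values are meaningful ("preventive" causes) and
are never clamped. Indeterminate forms ($0/0$, $\log(0/0)$) are flagged
`defined = FALSE` with an `NA` value; genuine infinities ($\pm\infty$)
remain `defined = TRUE`. Cheng's measure is flagged undefined whenever
$v = 0$, since the causal-power interpretation breaks down when the effect
is already certain without the cause.

### Expectations

`cs_expectation()` averages a per-transition measure over the joint
$P(c,e) = P_w(c) P(e|c)$. The cause weighting $P_w$ defaults to the
stationary distribution; the intervention distribution entering each term
may independently be maxent, observational, or cause-centered local.
Zero-probability transitions contribute nothing and are skipped; an
undefined included term, or included $+\infty$ and $-\infty$ terms
together, make the whole expectation undefined.

One measure gets special treatment. For the Lewis ratio the weighted term
cancels algebraically,
$P(c,e)\frac{s+v-1}{s} = P_w(c)\,[P(e|c) - P(e|C\setminus c)]$, and this
cancelled form is also the continuous limit of weight × value as
$P(e|c) \to 0$. Summing it over all effects gives
$P_w(c)(1-1) = 0$ for every cause, so the Lewis expectation is identically
zero for *any* TPM and *any* intervention distribution — the measure's
average carries no information, only its per-transition values do. The
package computes the expectation in cancelled form so this analytic
identity holds to machine precision; evaluating the raw ratio only on
positive-probability transitions would instead produce a support-dependent
positive number on sparse systems, which misrepresents the measure.

### Hamming-based measures

`cs_lewis_cpw()` takes the counterfactual to be the nearest state by
Hamming distance. The minimizer may be non-unique; the value is averaged
over all minimizers, which keeps the measure invariant under
label-permutation symmetries. `cs_bit_flip()` implements the mean Hamming
displacement of the effect under single-bit perturbations of the cause,
$\frac1N \sum_i \sum_{e'} P(e'|c[i])\,D_H(e, e')$, and requires the full
hypercube so every flipped label is a state. It is the one catalogue entry
that uses no intervention distribution and no causal primitive, and it is
deliberately left sensitive to the arbitrary state labeling rather than
"corrected" — that sensitivity is a documented property of the measure.

## Numerical conventions

* **Stationary distributions.** The bipartite model has period 2, so the
  literal iterate limit $\mu_0 T^k$ does not converge; the package returns
  the fixed point of $\pi = \pi T$, selected as the Cesàro (time-averaged)
  limit from the uniform start. It is computed by power iteration on the
  half-lazy kernel $(I+T)/2$, which has the same fixed points, damps the
  periodic oscillation, and converges geometrically to the same projection
  — so the default tolerance of $10^{-12}$ on
  $\max|\pi T - \pi|$ is reachable within the $10^5$-iteration cap, which
  plain running averages (converging like $1/k$) could not do. For
  reducible chains with several fixed points the from-uniform Cesàro choice
  is a convention; it is recorded in the distribution's metadata.
* **Validation.** TPM rows must sum to 1 within $10^{-9}$; rows inside the
  tolerance are renormalized, anything worse is rejected with the row
  named. Probabilities are validated on construction and trusted
  afterwards.
* **State order and bit labels.** Rows, columns, and weight vectors all
  follow the state space's label order. Binary labels are strings with the
  most-significant bit first; bit $i$ counts 1-based from the left.
* **Serialization.** In CSV output infinities are written `inf`/`-inf` and
  undefined values as empty cells beside a `defined` column, so results
  round-trip without NaN leakage.

## The model zoo

`bipartite_model(n_a, n_b, dilution, rewiring)` generates the two-group
oscillator used for parameter sweeps. States transition only into the
opposite group, so the coarse-graining that maps group A to `ON` and group
B to `OFF` yields the fixed macro TPM
$\begin{pmatrix}0&1\\1&0\end{pmatrix}$ at *every* parameter setting —
deterministic, non-degenerate, and dynamically consistent by construction
(the `supervenience_check()` residual is identically zero). That fixed
macroscale is the model's point: microscale noise can be varied while the
macroscale comparison stays constant.

The dilution parameter $d$ concentrates each row's mass on a main target
($d + (1-d)/n_{\mathrm{opp}}$, remainder uniform in the opposite group):
$d=0$ is uniform within-group noise, $d=1$ deterministic. The rewiring
parameter $g$ stacks main targets: the number of distinct targets is
$t = \max(1, \mathrm{round}((1-g) n))$, assigned round-robin onto the
first $t$ states of the opposite group, so $g=0$ is one-to-one and $g=1$
funnels every main transition into a single state. The two knobs move the
determinism and degeneracy coefficients along their respective axes
essentially independently. Bit labels follow the 16-state reference
convention (A = `0000`..`0111`, B = `1111` down to `1000`), which places
`0000`'s main transition at `1111` and its first secondary transition at
`1110`. Asymmetric group sizes use the same generator unchanged.

`nand_model(n_nodes, noise)` builds a Boolean network in which each gate's
next value is the NAND of all gates' previous values, so any state
containing a zero maps to all-ones and all-ones maps to all-zeros — a
bistable skeleton. Noise is applied at the state level: the logical target
keeps $1-\varepsilon$ and the rest is spread uniformly over the other
$2^n - 1$ states. The state-level convention (rather than independent
per-gate flips) is what makes the two-gate network at $\varepsilon = 0.1$
have $P(00 \mid 11) = 0.9$ exactly, matching the model's defining
probability; per-gate flips would give $0.81$. For more than two gates the
all-gates wiring (each gate reading every gate, itself included) is a
choice the two-gate case cannot distinguish from "all other gates"; the
self-inclusive version is used because it preserves the bistable dynamic at
every size, whereas excluding self-input creates spurious fixed points from
three gates up.

Both generators are deterministic functions of their parameters — no
sampling anywhere — so every table the package emits is exactly
reproducible.

## Causal emergence

`coarse_grain()` aggregates a micro TPM onto macrostates,
$P(y|x) = \sum_{c \in h^{-1}(x)} w_x(c) \sum_{e \in h^{-1}(y)} P(e|c)$.
The aggregation weights $w_x$ default to uniform within each macrostate
and may be taken from an intervention distribution (restricted and
renormalized per macrostate). For the bundled model families the choice is
irrelevant — all micro rows within a macrostate induce the same macro row,
which `supervenience_check()` verifies — but for general TPMs it is a real
modeling decision, which is why it is an explicit argument rather than a
hidden default.

`causal_emergence()` computes $CE = CS_{\mathrm{macro}} - CS_{\mathrm{micro}}$
for a measure, either for one micro transition against its macro image or
in expectation. Micro and macro intervention kinds are paired by tag by
default (maxent with maxent, and so on) and can be overridden. Three
conventions matter:

* **Macro Hamming structure.** A macro space has no intrinsic bit labels,
  so macrostates receive fresh minimal-width binary codes in macrostate
  order whenever a local intervention or a Hamming-based measure is
  evaluated at the macroscale. With two macrostates and $\Delta \ge 1$ the
  local distribution covers the whole macro space and coincides with
  maxent, as it must.
* **Infinite emergence.** A $-\infty$ micro value against a finite macro
  value yields $CE = +\infty$: a micro transition acting as an absolute
  preventive cause whose macro image is a positive cause. Opposite-signed
  infinities subtract to flagged-undefined, never to NaN.
* **Bit-flip across scales.** The bit-flip measure is denominated in label
  bits, and a 4-bit microscale and 1-bit macroscale are not commensurable:
  the raw microscale value is bounded below by 1 on the bipartite family
  (every cross-group displacement costs at least the group-indicator bit)
  while the raw macroscale value is pinned at 1, which would make bit-flip
  emergence structurally impossible — an artifact of units, not of
  causation. Within a scale the raw formula is used verbatim; for the
  cross-scale CE comparison each scale's value is divided by its own label
  width, giving a mean per-bit displacement. Under this normalization the
  bit-flip measure exhibits positive CE on the sweep, consistent with its
  known behavior as the catalogue's outlier (it is also the one measure
  not built from the causal primitives).

`ce_sweep()` tabulates CE over a dilution × rewiring lattice (default
11 × 11, the full catalogue, three scopes: the reference state's main
transition, its first secondary transition, and the expectation). The
default intervention is local with $\Delta = 1$ — the minimal neighborhood
that is strictly richer than the single closest world — with maxent and
observational available for comparison; the default expectation weighting
is the stationary distribution at each scale.
`normalized_average_ce()` rescales each measure by its own maximum finite
$|CE|$ over the supplied table before averaging across measures, since the
measures' units are incommensurable; non-finite cells are excluded from
the average (Good's measure, for instance, yields $+\infty$ CE against any
fully deterministic, fully necessary macro transition, at every grid
point).

## What the model systems do and do not show

The generators realize the study conditions the package is designed
around: a 16-state symmetric bipartite microscale (groups of 8) against a
fixed two-state macroscale, and a 4-to-16-state NAND hypercube against an
ON/all-else grouping. Passing tests on these systems demonstrates the
internal consistency of the measures and the existence and parameter
dependence of causal emergence under fully known dynamics. They do not
demonstrate anything about estimation: real systems hand you samples, not
TPMs, and the package deliberately contains no estimator of a TPM from
data, no confidence intervals, and no correction for the (large)
uncertainty such estimation would introduce. Nor is there any search over
candidate coarse-grainings — the macroscale must be supplied, and the
package only scores it. Continuous state spaces, time-inhomogeneous
chains, and multi-scale apportioning of causal contributions are out of
scope.

## Known limitations

* Lewis's normalized ratio $(s+v-1)/s$ is described as ranging over
  $[-1, 1]$, but it is unbounded below as $s \to 0$; the package reports
  the unbounded values as-is.
* Good's measure is defined up to the logarithm base; base 2 is used so
  that all information-valued measures share units (bits).
* The Galton prefactor $P_C(c)(1 - P_C(c))$ comes from a binary indicator
  decomposition; it is applied at face value for arbitrary $n$.
* Observational distributions of reducible chains depend on the
  from-uniform Cesàro convention; other conventions would pick different
  fixed points.
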