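#' Causal primitives
#'
#' The four building blocks shared by every catalogued measure of causation:
#'
#' * **sufficiency** `suff(e,c) = P(e|c)` -- how capable the cause is of
#'   producing the effect;
#' * **necessity** `nec(e,c) = 1 - P(e|C\c)` -- how irreplaceable the cause
#'   is (1 when nothing else can produce the effect);
#' * **determinism** -- the information-theoretic extension of sufficiency:
#'   how concentrated a cause's effect distribution is;
#' * **degeneracy** -- the extension of (inverse) necessity: how strongly
#'   effects are shared targets of many causes.
#'
#' Entropies are in bits and the normalizing `log2(n)` always uses the size
#' of the full state space. The convention `0 * log2(1/0) = 0` applies.
#'
#' @name causal_primitives
NULL

# Shannon entropy in bits with 0 log 0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @describeIn causal_primitives Sufficiency `P(e|c)` of cause `cause` for
#'   effect `effect`.
#' @param model A [transition_model()].
#' @param pc An `intervention_distribution` over the same space.
#' @param cause,effect State labels.
#' @return A numeric scalar.
#' @export
sufficiency <- function(model, cause, effect) {
  trans_prob(model, cause, effect)
}

#' @describeIn causal_primitives Necessity `1 - P(e|C\c)`.
#' @export
necessity <- function(model, pc, cause, effect) {
  pe <- counterfactual_effect_distribution(model, pc, cause)
  1 - pe[[state_index(model$space, effect)]]
}

#' @describeIn causal_primitives Softened necessity `nec_dagger(e) = P(e|C)`,
#'   the marginal probability of the effect under the intervention
#'   distribution.
#' @export
nec_dagger <- function(model, pc, effect) {
  marginal_effect_distribution(model, pc)[[state_index(model$space, effect)]]
}

#' @describeIn causal_primitives Determinism coefficient of a cause,
#'   `det(c) = 1 - H(E|c) / log2(n)`: 1 for a deterministic row, 0 for a
#'   uniform row.
#' @export
determinism_state <- function(model, cause) {
  n <- model$space$n
  row <- model$matrix[state_index(model$space, cause), ]
  1 - entropy_bits(row) / log2(n)
}

#' @describeIn causal_primitives Per-transition determinism
#'   `det(e,c) = 1 - log2(1/P(e|c)) / log2(n)`; `-Inf` when `P(e|c) = 0`.
#' @export
determinism_transition <- function(model, cause, effect) {
  n <- model$space$n
  p <- trans_prob(model, cause, effect)
  if (p == 0) return(-Inf)
  1 - log2(1 / p) / log2(n)
}

#' @describeIn causal_primitives System-level determinism
#'   `det = sum_c P_C(c) det(c)`, the intervention-weighted average of the
#'   per-cause coefficients.
#' @export
determinism_system <- function(model, pc) {
  check_same_space(model, pc)
  n <- model$space$n
  h <- apply(model$matrix, 1L, entropy_bits)
  1 - sum(pc$weights * h) / log2(n)
}

#' @describeIn causal_primitives Per-effect degeneracy
#'   `deg(e) = 1 - log2(1/P(e|C)) / log2(n)`; `-Inf` when `P(e|C) = 0`.
#' @export
degeneracy_effect <- function(model, pc, effect) {
  n <- model$space$n
  p <- nec_dagger(model, pc, effect)
  if (p == 0) return(-Inf)
  1 - log2(1 / p) / log2(n)
}

#' @describeIn causal_primitives System-level degeneracy
#'   `deg = 1 - H(E|C) / log2(n)`, from the entropy of the marginal effect
#'   distribution.
#' @export
degeneracy_system <- function(model, pc) {
  n <- model$space$n
  1 - entropy_bits(marginal_effect_distribution(model, pc)) / log2(n)
}

#' Full primitive profile of a transition
#'
#' Convenience wrapper collecting transition-, state- and system-level
#' primitives for one `(cause, effect)` pair under one intervention
#' distribution.
#'
#' @inheritParams causal_primitives
#' @return A one-row data frame with columns `suff`, `nec`, `nec_dagger`,
#'   `det_transition`, `det_state`, `deg_effect`, `det_system`, `deg_system`.
#' @export
primitive_profile <- function(model, pc, cause, effect) {
  data.frame(
    cause = cause, effect = effect,
    suff = sufficiency(model, cause, effect),
    nec = necessity(model, pc, cause, effect),
    nec_dagger = nec_dagger(model, pc, effect),
    det_transition = determinism_transition(model, cause, effect),
    det_state = determinism_state(model, cause),
    deg_effect = degeneracy_effect(model, pc, effect),
    det_system = determinism_system(model, pc),
    deg_system = degeneracy_system(model, pc),
    stringsAsFactors = FALSE
  )
}
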