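#' Intervention distributions over causes
#'
#' An intervention distribution P_C is a probability vector over the states of
#' a space, representing the set of (hypothetical) interventions used to probe
#' counterfactuals. Three constructions are supported, mirroring the three
#' standard modeling choices:
#'
#' * [maxent_distribution()] -- the maximum-entropy (uniform) distribution,
#'   every state equally intervened on;
#' * [observational_distribution()] -- the stationary distribution of the
#'   chain, i.e. the fixed point of `pi = pi %*% T`;
#' * [local_distribution()] -- uniform over the Hamming ball of radius
#'   `delta` around a center state (local perturbations of the actual state);
#' * [custom_distribution()] -- arbitrary user weights.
#'
#' @name intervention_distribution
#' @return An object of class `intervention_distribution` with elements
#'   `space`, `weights` (named, non-negative, summing to 1), `kind` (one of
#'   `"maxent"`, `"observational"`, `"local"`, `"custom"`) and `params`.
NULL

new_intervention <- function(space, weights, kind, params = list()) {
  weights <- as.numeric(weights)
  if (length(weights) != space$n || anyNA(weights) || any(weights < 0)) {
    stop("intervention weights must be a non-negative vector over the space",
         call. = FALSE)
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    stop("intervention weights must sum to 1 (got ", format(s), ")",
         call. = FALSE)
  }
  weights <- weights / s
  names(weights) <- space$labels
  structure(
    list(space = space, weights = weights, kind = kind, params = params),
    class = "intervention_distribution"
  )
}

#' @export
print.intervention_distribution <- function(x, ...) {
  cat("Intervention distribution (", x$kind, ") over ", x$space$n,
      " states\n", sep = "")
  supp <- x$weights[x$weights > 0]
  show <- utils::head(supp, 8L)
  cat(paste0("  P(", names(show), ") = ", signif(show, 4), collapse = "\n"),
      "\n")
  if (length(supp) > 8L) cat("  ...\n")
  invisible(x)
}

#' Maximum-entropy intervention distribution
#'
#' Uniform weight 1/n on every state: all interventions considered equally,
#' independent of the system's own dynamics.
#'
#' @param space A [state_space()].
#' @return An `intervention_distribution` of kind `"maxent"`.
#' @export
maxent_distribution <- function(space) {
  new_intervention(space, rep(1 / space$n, space$n), "maxent")
}

#' Observational (stationary) intervention distribution
#'
#' The long-run distribution of the chain: the fixed point of
#' `pi = pi %*% T`. For periodic chains, whose literal iterate limit does not
#' exist, and for reducible chains with several fixed points, the returned
#' vector is the Cesaro (time-averaged) limit started from the uniform
#' distribution. It is computed by power iteration on the half-lazy kernel
#' `(I + T)/2`, which shares T's fixed points, damps periodic oscillation, and
#' converges geometrically to the same Cesaro projection.
#'
#' @param model A [transition_model()].
#' @param tolerance Convergence tolerance on `max|pi T - pi|` (default
#'   `1e-12`).
#' @param max_iter Iteration cap (default `1e5`).
#' @return An `intervention_distribution` of kind `"observational"`; its
#'   `params` carry the residual, iteration count, and the from-uniform
#'   convention flag.
#' @export
observational_distribution <- function(model, tolerance = 1e-12,
                                       max_iter = 1e5) {
  T_ <- model$matrix
  n <- nrow(T_)
  pi_ <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    nxt <- as.numeric(pi_ %*% T_)
    lazy <- (pi_ + nxt) / 2
    resid <- max(abs(nxt - pi_))
    lazy_step <- max(abs(lazy - pi_))
    pi_ <- lazy
    if (resid <= tolerance || lazy_step <= tolerance / 4) break
    if (iter >= max_iter) {
      stop("stationary distribution did not converge after ", iter,
           " iterations (residual ", format(resid), ")", call. = FALSE)
    }
  }
  pi_ <- pi_ / sum(pi_)
  resid <- max(abs(as.numeric(pi_ %*% T_) - pi_))
  if (resid > sqrt(tolerance)) {
    stop("stationary fixed point residual too large: ", format(resid),
         call. = FALSE)
  }
  new_intervention(model$space, pi_, "observational",
                   params = list(residual = resid, iterations = iter,
                                 start = "uniform-cesaro"))
}

#' Local (Hamming-ball) intervention distribution
#'
#' Uniform weights on all states within Hamming distance `delta` of a center
#' state (the center included), zero elsewhere: only perturbations "close" to
#' the actual state are treated as viable counterfactual interventions.
#'
#' @param space A [state_space()] with binary labels.
#' @param center Binary label of the actual state.
#' @param delta Non-negative integer radius.
#' @return An `intervention_distribution` of kind `"local"`; `params` carry
#'   the center, radius, and support size `n_delta`.
#' @examples
#' sp <- state_space(c("000", "001", "010", "011", "100", "101", "110", "111"))
#' local_distribution(sp, "001", 1) # support {001, 101, 011, 000}, each 1/4
#' @export
local_distribution <- function(space, center, delta) {
  if (!has_bits(space)) {
    stop("local interventions need a space with binary labels", call. = FALSE)
  }
  delta <- as.integer(delta)
  if (delta < 0) stop("delta must be a non-negative integer", call. = FALSE)
  state_index(space, center)
  d <- hamming_to_all(space, center)
  supp <- d <= delta
  w <- ifelse(supp, 1 / sum(supp), 0)
  new_intervention(space, w, "local",
                   params = list(center = center, delta = delta,
                                 n_delta = sum(supp)))
}

#' Custom intervention distribution
#'
#' @param space A [state_space()].
#' @param weights Non-negative numeric vector over the space (label order),
#'   summing to 1; a named vector is reordered to the space's label order.
#' @return An `intervention_distribution` of kind `"custom"`.
#' @export
custom_distribution <- function(space, weights) {
  if (!is.null(names(weights))) {
    i <- state_index(space, names(weights))
    w <- numeric(space$n)
    w[i] <- weights
    weights <- w
  }
  new_intervention(space, weights, "custom")
}

check_same_space <- function(model, pc) {
  if (!identical(model$space$labels, pc$space$labels)) {
    stop("transition model and intervention distribution are defined over ",
         "different state spaces", call. = FALSE)
  }
}

#' Marginal effect distribution P(e|C)
#'
#' The probability of each effect when the cause is drawn from the
#' intervention distribution: `P(e|C) = sum_c P_C(c) P(e|c)`.
#'
#' @param model A [transition_model()].
#' @param pc An `intervention_distribution` over the same space.
#' @return Named probability vector over effects.
#' @export
marginal_effect_distribution <- function(model, pc) {
  check_same_space(model, pc)
  as.numeric(pc$weights %*% model$matrix) |> stats::setNames(model$space$labels)
}

#' Counterfactual effect distribution P(e|C\\c)
#'
#' The effect distribution when the cause is drawn from the intervention
#' distribution renormalized to exclude a given cause:
#' `P(e|C\c) = sum_{c' != c} [P_C(c') / (1 - P_C(c))] P(e|c')`.
#' If the excluded cause carries no intervention mass the renormalization is
#' the identity and `P(e|C\c) = P(e|C)`.
#'
#' @param model A [transition_model()].
#' @param pc An `intervention_distribution` over the same space.
#' @param excluded State label of the cause being negated.
#' @return Named probability vector over effects.
#' @export
counterfactual_effect_distribution <- function(model, pc, excluded) {
  check_same_space(model, pc)
  i <- state_index(model$space, excluded)
  mass <- pc$weights[i]
  if (mass >= 1 - 1e-12) {
    stop("degenerate counterfactual: P_C(", excluded, ") = 1 leaves no ",
         "alternative causes", call. = FALSE)
  }
  w <- pc$weights
  w[i] <- 0
  w <- w / (1 - mass)
  as.numeric(w %*% model$matrix) |> stats::setNames(model$space$labels)
}
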