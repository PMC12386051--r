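#' Bipartite Markov chain with tunable determinism and degeneracy
#'
#' Generates the two-group oscillator used throughout the package as a test
#' bed: states split into group A and group B, and every state transitions
#' only into the opposite group, so the ON/OFF coarse-graining is perfectly
#' deterministic at the macroscale regardless of the microscale parameters.
#'
#' Two independent knobs shape the microscale noise:
#'
#' * **dilution** `d` (determinism axis): each cause's *main target* in the
#'   opposite group receives probability `d + (1 - d)/n_opp` while every
#'   other opposite-group state receives `(1 - d)/n_opp`. At `d = 0` rows are
#'   uniform within the opposite group; at `d = 1` they are deterministic.
#' * **rewiring** `g` (degeneracy axis): the main-target map is rewired so
#'   only `t = max(1, round((1 - g) * n))` distinct targets remain, assigned
#'   round-robin onto the first `t` states of the opposite group. At `g = 0`
#'   the map is one-to-one (for equal group sizes); at `g = 1` all main
#'   transitions stack onto a single shared target.
#'
#' Bit labels follow the grouping convention of the 16-state reference
#' system: group A gets the binary codes of `0 .. n_a-1` and group B the
#' codes of `n-1` down to `n_a` (so for `n = 16`, A = 0000..0111 and
#' B = 1111 down to 1000, and the main transition of 0000 is 0000 -> 1111).
#'
#' @param n_a,n_b Group sizes (default 8 and 8, the 16-state reference
#'   system).
#' @param dilution `d` in `[0, 1]`.
#' @param rewiring `g` in `[0, 1]`.
#' @return A [transition_model()] whose space carries binary labels; the
#'   attribute `groups` holds the A/B membership and `main_map` the main
#'   target of every state.
#' @examples
#' m <- bipartite_model(dilution = 0.5, rewiring = 0)
#' bipartite_transitions(m, "0000")
#' @export
bipartite_model <- function(n_a = 8, n_b = 8, dilution, rewiring) {
  if (n_a < 1 || n_b < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (dilution < 0 || dilution > 1 || rewiring < 0 || rewiring > 1) {
    stop("dilution and rewiring must lie in [0, 1]", call. = FALSE)
  }
  n <- n_a + n_b
  width <- max(1L, ceiling(log2(n)))
  labels_a <- int_to_bits(seq_len(n_a) - 1L, width)
  labels_b <- int_to_bits(rev(seq(n_a, n - 1L)), width)
  labels <- c(labels_a, labels_b)
  space <- state_space(labels, bit_width = width)

  main_of <- function(n_from, n_to, g) {
    t <- max(1L, round((1 - g) * n_from))
    t <- min(t, n_to)
    ((seq_len(n_from) - 1L) %% t) + 1L  # round-robin onto first t targets
  }
  m_a <- main_of(n_a, n_b, rewiring)  # A-state i -> B index m_a[i]
  m_b <- main_of(n_b, n_a, rewiring)

  tpm <- matrix(0, n, n, dimnames = list(labels, labels))
  base_b <- (1 - dilution) / n_b
  base_a <- (1 - dilution) / n_a
  for (i in seq_len(n_a)) {
    tpm[i, n_a + seq_len(n_b)] <- base_b
    tpm[i, n_a + m_a[i]] <- tpm[i, n_a + m_a[i]] + dilution
  }
  for (j in seq_len(n_b)) {
    tpm[n_a + j, seq_len(n_a)] <- base_a
    tpm[n_a + j, m_b[j]] <- tpm[n_a + j, m_b[j]] + dilution
  }

  model <- transition_model(tpm, space)
  attr(model, "groups") <- list(A = labels_a, B = labels_b)
  attr(model, "main_map") <- stats::setNames(
    c(labels_b[m_a], labels_a[m_b]), labels
  )
  attr(model, "params") <- list(n_a = n_a, n_b = n_b, dilution = dilution,
                                rewiring = rewiring)
  model
}

#' Main and secondary transition of a bipartite-model state
#'
#' The *main* transition is the cause's highest-probability transition (its
#' main target under the dilution scheme); the *secondary* transition goes to
#' the first opposite-group state, in label order, that is not the main
#' target. Requires `dilution > 0`, otherwise no transition dominates.
#'
#' @param model A [bipartite_model()].
#' @param cause State label.
#' @return A list with `main` and `secondary`, each `c(cause, effect)`.
#' @export
bipartite_transitions <- function(model, cause) {
  params <- attr(model, "params")
  if (is.null(params)) {
    stop("model was not built by bipartite_model()", call. = FALSE)
  }
  if (params$dilution <= 0) {
    stop("no unique main transition at dilution 0 (all targets tie)",
         call. = FALSE)
  }
  groups <- attr(model, "groups")
  main <- attr(model, "main_map")[[cause]]
  opp <- if (cause %in% groups$A) groups$B else groups$A
  secondary <- opp[opp != main][1L]
  list(main = c(cause = cause, effect = main),
       secondary = c(cause = cause, effect = secondary))
}

#' Coarse-graining of the bipartite model onto ON/OFF
#'
#' @param model A [bipartite_model()].
#' @return A [coarse_graining()] mapping group A to `ON` and group B to
#'   `OFF`.
#' @export
bipartite_macro_mapping <- function(model) {
  groups <- attr(model, "groups")
  if (is.null(groups)) {
    stop("model was not built by bipartite_model()", call. = FALSE)
  }
  mapping <- stats::setNames(
    c(rep("ON", length(groups$A)), rep("OFF", length(groups$B))),
    c(groups$A, groups$B)
  )
  coarse_graining(model$space, mapping[model$space$labels])
}

#' Noisy NAND Boolean network
#'
#' A network of `n_nodes` binary gates in which every gate's next value is
#' the NAND of all gates' previous values. Any state containing a 0 therefore
#' maps to the all-ones state, and the all-ones state maps to all-zeros,
#' giving a bistable deterministic skeleton. Noise is applied at the state
#' level: the logical target keeps probability `1 - noise` and the remaining
#' mass is spread uniformly over the other `2^n - 1` states.
#'
#' @param n_nodes Number of gates (>= 2).
#' @param noise State-level noise in `[0, 1]`.
#' @return A [transition_model()] over the full `2^n_nodes` hypercube.
#' @examples
#' nand_model(2, 0.1) # P(00 | 11) = 0.9
#' @export
nand_model <- function(n_nodes, noise) {
  if (n_nodes < 2) stop("need at least 2 gates", call. = FALSE)
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]", call. = FALSE)
  n <- 2L^n_nodes
  labels <- int_to_bits(0:(n - 1L), n_nodes)
  space <- state_space(labels, bit_width = n_nodes)
  all_ones <- labels[n]
  all_zeros <- labels[1L]
  tpm <- matrix(noise / (n - 1L), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    target <- if (labels[i] == all_ones) all_zeros else all_ones
    tpm[i, ] <- noise / (n - 1L)
    tpm[i, target] <- 1 - noise
  }
  model <- transition_model(tpm, space)
  attr(model, "params") <- list(n_nodes = n_nodes, noise = noise)
  model
}

#' Coarse-graining of the NAND network onto ON/OFF
#'
#' Groups the all-ones microstate into macrostate `ON` and every other
#' microstate into `OFF`.
#'
#' @param model A [nand_model()].
#' @return A [coarse_graining()].
#' @export
nand_macro_mapping <- function(model) {
  labels <- model$space$labels
  all_ones <- strrep("1", model$space$bit_width)
  mapping <- stats::setNames(ifelse(labels == all_ones, "ON", "OFF"), labels)
  coarse_graining(model$space, mapping)
}
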