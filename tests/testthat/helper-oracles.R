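# Fixtures and independent brute-force oracles. Oracles are deliberately
# written as explicit loops over the definitions, not through the package's
# own kernels.

# Two-state switch/bulb system: state 1 is "switch up, bulb on", state 2
# "switch down, bulb off"; each cause deterministically produces its bulb
# state. P(ON|UP) = 1, P(OFF|DOWN) = 1.
light_switch <- function() {
  transition_model(
    matrix(c(1, 0,
             0, 1), 2, byrow = TRUE),
    state_space(c("ON", "OFF"))  # cause UP realized as ON, DOWN as OFF
  )
}

# Random row-stochastic matrix with full support.
random_tpm <- function(n, labels = NULL, sparsify = 0) {
  m <- matrix(stats::rexp(n * n), n, n)
  if (sparsify > 0) {
    zero <- matrix(stats::runif(n * n) < sparsify, n, n)
    # keep at least one positive entry per row
    for (i in seq_len(n)) if (all(zero[i, ])) zero[i, sample(n, 1)] <- FALSE
    m[zero] <- 0
  }
  m <- m / rowSums(m)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  dimnames(m) <- list(labels, labels)
  transition_model(m, state_space(labels))
}

random_pc <- function(space) {
  w <- stats::rexp(space$n)
  custom_distribution(space, w / sum(w))
}

# --- oracles ---------------------------------------------------------------

oracle_marginal <- function(model, pc) {
  n <- model$space$n
  out <- numeric(n)
  for (e in seq_len(n)) {
    for (c in seq_len(n)) out[e] <- out[e] + pc$weights[c] * model$matrix[c, e]
  }
  out
}

oracle_counterfactual <- function(model, pc, excluded_idx) {
  n <- model$space$n
  denom <- 1 - pc$weights[excluded_idx]
  out <- numeric(n)
  for (e in seq_len(n)) {
    for (c in seq_len(n)) {
      if (c == excluded_idx) next
      out[e] <- out[e] + pc$weights[c] / denom * model$matrix[c, e]
    }
  }
  out
}

oracle_entropy <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log2(x)
  s
}

oracle_coarse_grain <- function(model, map, micro_w = NULL) {
  macro_labels <- unique(unname(map))
  k <- length(macro_labels)
  if (is.null(micro_w)) micro_w <- rep(1, model$space$n)
  out <- matrix(0, k, k, dimnames = list(macro_labels, macro_labels))
  for (x in seq_len(k)) {
    members <- which(map == macro_labels[x])
    w <- micro_w[members] / sum(micro_w[members])
    for (y in seq_len(k)) {
      tgt <- which(map == macro_labels[y])
      acc <- 0
      for (mi in seq_along(members)) {
        acc <- acc + w[mi] * sum(model$matrix[members[mi], tgt])
      }
      out[x, y] <- acc
    }
  }
  out
}

# Covariance of the indicator variables X_c, Y_e under joint P_C(c) P(e|c).
oracle_galton_cov <- function(model, pc, ci, ei) {
  n <- model$space$n
  exy <- pc$weights[ci] * model$matrix[ci, ei]
  ex <- pc$weights[ci]
  ey <- 0
  for (c in seq_len(n)) ey <- ey + pc$weights[c] * model$matrix[c, ei]
  unname(exy - ex * ey)
}

oracle_bit_flip <- function(model, cause, effect) {
  N <- model$space$bit_width
  labels <- model$space$labels
  total <- 0
  for (i in seq_len(N)) {
    flipped <- flip_label_bit(cause, i)
    ci <- match(flipped, labels)
    for (e2 in seq_len(length(labels))) {
      total <- total + model$matrix[ci, e2] *
        sum(strsplit(effect, "")[[1]] != strsplit(labels[e2], "")[[1]])
    }
  }
  total / N
}

flip_label_bit <- function(label, i) {
  b <- strsplit(label, "")[[1]]
  b[i] <- if (b[i] == "0") "1" else "0"
  paste(b, collapse = "")
}

# Stationary distribution by eigen-decomposition of t(T).
oracle_stationary <- function(model) {
  e <- eigen(t(model$matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
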