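#' Construct a transition model (TPM)
#'
#' A transition model is a row-stochastic transition probability matrix over a
#' finite state space: entry `[c, e]` is `P(e | do(c))`, the probability that
#' intervening to set the system to state `c` at time t yields state `e` at
#' time t+1. The TPM is the complete causal model of the system; every
#' primitive and measure in the package is computed from it.
#'
#' Rows must sum to 1 within `tolerance`; rows off by no more than the
#' tolerance are renormalized, anything worse is rejected.
#'
#' @param matrix Numeric n x n matrix, rows indexed by cause, columns by
#'   effect. Row/column names, if present, must agree with `space`.
#' @param space A [state_space()]; defaults to the matrix dimnames (or
#'   auto-generated binary labels when the dimension is a power of two is NOT
#'   assumed -- unlabeled matrices get `s1..sn`).
#' @param tolerance Row-sum validation tolerance (default `1e-9`).
#' @return An object of class `transition_model` with elements `space` and
#'   `matrix` (dimnames set to the state labels).
#' @examples
#' light_switch <- transition_model(
#'   matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
#'   state_space(c("DOWN", "UP"))
#' )
#' @export
transition_model <- function(matrix, space = NULL, tolerance = 1e-9) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) {
    stop("a TPM must be square (one row and one column per state)",
         call. = FALSE)
  }
  if (is.null(space)) {
    lab <- rownames(m)
    if (is.null(lab)) lab <- paste0("s", seq_len(nrow(m)))
    space <- state_space(lab)
  }
  if (space$n != nrow(m)) {
    stop("state space has ", space$n, " states but TPM is ", nrow(m), "x",
         ncol(m), call. = FALSE)
  }
  if (!is.null(rownames(m)) && !identical(rownames(m), space$labels)) {
    stop("TPM row names disagree with the state space label order",
         call. = FALSE)
  }
  if (anyNA(m) || any(m < -tolerance) || any(m > 1 + tolerance)) {
    stop("TPM entries must be probabilities in [0, 1]", call. = FALSE)
  }
  m[m < 0] <- 0
  rs <- rowSums(m)
  bad <- abs(rs - 1) > tolerance
  if (any(bad)) {
    stop("TPM row(s) not summing to 1 within tolerance: ",
         paste(space$labels[bad], collapse = ", "), call. = FALSE)
  }
  m <- m / rs
  dimnames(m) <- list(space$labels, space$labels)
  structure(list(space = space, matrix = m), class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition model over", x$space$n, "states")
  if (has_bits(x$space)) {
    cat(" (", x$space$bit_width, "-bit labels)", sep = "")
  }
  cat("\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# P(e|c) for a single transition.
trans_prob <- function(model, cause, effect) {
  model$matrix[state_index(model$space, cause),
               state_index(model$space, effect)]
}
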