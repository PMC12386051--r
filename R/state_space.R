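#' Construct a finite state space
#'
#' A state space is the finite set of labeled system states over which a
#' Markovian causal model is defined. Labels may optionally be fixed-width
#' binary strings, in which case the space carries a Hamming metric that the
#' local intervention distribution and the distance-based measures
#' (closest-possible-world Lewis, bit-flip) rely on.
#'
#' @param labels Character vector of distinct state identifiers (length >= 2).
#' @param bit_width Optional integer. If supplied, every label must be a
#'   binary string of exactly this many characters. If `NULL`, a width is
#'   auto-detected when all labels are equal-length binary strings.
#' @return An object of class `state_space` with elements `labels`, `n`, and
#'   `bit_width` (`NA` when labels carry no binary structure).
#' @examples
#' state_space(c("UP", "DOWN"))
#' state_space(c("00", "01", "10", "11"))
#' @export
state_space <- function(labels, bit_width = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("state labels must be unique", call. = FALSE)
  }
  if (length(labels) < 2) {
    stop("a state space needs at least 2 states", call. = FALSE)
  }
  binary <- all(grepl("^[01]+$", labels)) && length(unique(nchar(labels))) == 1L
  if (is.null(bit_width)) {
    bit_width <- if (binary) nchar(labels[[1L]]) else NA_integer_
  } else {
    bit_width <- as.integer(bit_width)
    if (!binary || nchar(labels[[1L]]) != bit_width) {
      stop("bit_width set but labels are not binary strings of that width",
           call. = FALSE)
    }
    if (length(labels) > 2^bit_width) {
      stop("more labels than the ", bit_width, "-bit hypercube holds",
           call. = FALSE)
    }
  }
  structure(
    list(labels = labels, n = length(labels), bit_width = bit_width),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space with", x$n, "states")
  if (!is.na(x$bit_width)) cat(" (", x$bit_width, "-bit labels)", sep = "")
  cat("\n  ", paste(utils::head(x$labels, 8L), collapse = ", "))
  if (x$n > 8L) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
length.state_space <- function(x) x$n

has_bits <- function(space) !is.na(space$bit_width)

state_index <- function(space, label) {
  i <- match(label, space$labels)
  if (anyNA(i)) {
    stop("unknown state label(s): ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Hamming distance between two binary state labels
#'
#' Number of bit flips needed to turn one binary string into the other,
#' i.e. `sum(|x_i - y_i|)` over bit positions. Bits are indexed 1-based from
#' the left (most-significant first).
#'
#' @param x,y Binary strings of equal length.
#' @return Non-negative integer distance.
#' @examples
#' hamming_distance("0001", "0010") # 2
#' @export
hamming_distance <- function(x, y) {
  if (!is.character(x) || !is.character(y) ||
      !grepl("^[01]+$", x) || !grepl("^[01]+$", y)) {
    stop("hamming_distance needs binary string labels", call. = FALSE)
  }
  if (nchar(x) != nchar(y)) {
    stop("labels differ in length (", nchar(x), " vs ", nchar(y), ")",
         call. = FALSE)
  }
  sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
}

# Pairwise Hamming distances from `label` to every state in the space.
hamming_to_all <- function(space, label) {
  stopifnot(has_bits(space))
  bits <- strsplit(space$labels, "")
  ref <- strsplit(label, "")[[1L]]
  if (length(ref) != space$bit_width) {
    stop("label width does not match the space's bit width", call. = FALSE)
  }
  vapply(bits, function(b) sum(b != ref), integer(1))
}

# Binary labels for 0..(n-1), most-significant bit first.
int_to_bits <- function(x, width) {
  vapply(x, function(v) {
    paste(rev(as.integer(intToBits(v)[seq_len(width)])), collapse = "")
  }, character(1))
}

# Flip the i-th bit (1-based from the left) of a binary label.
flip_bit <- function(label, i) {
  b <- strsplit(label, "")[[1L]]
  b[i] <- if (b[i] == "0") "1" else "0"
  paste(b, collapse = "")
}
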