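#' Measures of causal strength
#'
#' The package's catalogue of classical measures of causation, each expressed
#' through the causal primitives. With `s = suff(e,c) = P(e|c)`,
#' `v = nec(e,c) = 1 - P(e|C\c)` and `m = nec_dagger(e) = P(e|C)`:
#'
#' | measure | formula | origin |
#' |---|---|---|
#' | `galton` | `P_C(c)(1 - P_C(c)) (s + v - 1)` | Humean covariance |
#' | `eells` | `s + v - 1` | probability raising (difference) |
#' | `suppes` | `s - m` | probability raising vs. marginal |
#' | `cheng` | `(s + v - 1)/v` | causal power |
#' | `good` | `log2(v / (1 - s))` | weight of evidence |
#' | `lewis` | `(s + v - 1)/s` | normalized relative risk |
#' | `pearl_pns`, `pearl_pn`, `pearl_ps` | aliases of `eells`, `lewis`, `cheng` | probability of necessity/sufficiency |
#' | `lewis_cpw` | `(P(e|c) - P(e|cpw))/P(e|c)` | closest possible world |
#' | `bit_flip` | mean Hamming displacement under single-bit cause flips | perturbation sensitivity |
#' | `effect_information` | `log2(s/m)` | actual causation (bits) |
#'
#' Values may legitimately be negative ("preventive" causes) or infinite;
#' indeterminate forms (0/0, log(0/0)) are flagged `defined = FALSE` and carry
#' an `NA` value, never a silent zero.
#'
#' @name causal_measures
NULL

measure_result <- function(measure, cause, effect, value, defined = TRUE,
                           intervention = NA_character_) {
  value <- unname(value)
  if (!defined) value <- NA_real_
  structure(
    list(measure = measure, cause = cause, effect = effect,
         value = value, defined = defined, intervention = intervention),
    class = "measure_result"
  )
}

#' @export
print.measure_result <- function(x, ...) {
  tr <- if (identical(x$cause, "expectation")) "E[.]" else {
    paste0("(", x$cause, " -> ", x$effect, ")")
  }
  val <- if (!x$defined) "undefined" else format(x$value, digits = 6)
  cat(x$measure, " ", tr, " = ", val,
      if (!is.na(x$intervention)) paste0("  [", x$intervention, "]"), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.measure_result <- function(x, ...) {
  data.frame(measure = x$measure, cause = x$cause, effect = x$effect,
             intervention_kind = x$intervention, value = x$value,
             defined = x$defined, stringsAsFactors = FALSE)
}

#' Extract the numeric value of a measure result
#' @param x A `measure_result`.
#' @return Numeric scalar (`NA` when undefined, possibly `Inf`/`-Inf`).
#' @export
measure_value <- function(x) x$value

# --- raw kernels -----------------------------------------------------------
# Each returns list(value=, defined=) from the primitive values; kept separate
# from the user-facing wrappers so the expectation machinery can reuse them.

raw_eells <- function(s, v) list(value = s + v - 1, defined = TRUE)

raw_suppes <- function(s, m) list(value = s - m, defined = TRUE)

raw_cheng <- function(s, v) {
  if (v == 0) return(list(value = NA_real_, defined = FALSE))
  list(value = (s + v - 1) / v, defined = TRUE)
}

raw_good <- function(s, v) {
  if (s == 1 && v == 0) return(list(value = NA_real_, defined = FALSE))
  if (s == 1) return(list(value = Inf, defined = TRUE))
  if (v == 0) return(list(value = -Inf, defined = TRUE))
  list(value = log2(v / (1 - s)), defined = TRUE)
}

raw_lewis <- function(s, v) {
  if (s == 0) {
    # P(e|C\c) = 1 - v; the 0/0 form arises when both routes give zero
    if (v == 1) return(list(value = NA_real_, defined = FALSE))
    return(list(value = -Inf, defined = TRUE))
  }
  list(value = (s + v - 1) / s, defined = TRUE)
}

raw_ratio_drop <- function(p_c, p_alt) {
  # (p_c - p_alt)/p_c, shared by lewis_cpw
  if (p_c == 0) {
    if (p_alt == 0) return(list(value = NA_real_, defined = FALSE))
    return(list(value = -Inf, defined = TRUE))
  }
  list(value = (p_c - p_alt) / p_c, defined = TRUE)
}

raw_ei <- function(s, m) {
  if (s == 0 && m == 0) return(list(value = NA_real_, defined = FALSE))
  if (s == 0) return(list(value = -Inf, defined = TRUE))
  if (m == 0) return(list(value = Inf, defined = TRUE))
  list(value = log2(s / m), defined = TRUE)
}

sv_primitives <- function(model, pc, cause, effect) {
  list(
    s = sufficiency(model, cause, effect),
    v = necessity(model, pc, cause, effect),
    m = nec_dagger(model, pc, effect)
  )
}

# --- per-transition measures ----------------------------------------------

#' @describeIn causal_measures Galton / Humean covariance measure.
#' @param model A [transition_model()].
#' @param pc An `intervention_distribution` over the model's space.
#' @param cause,effect State labels of the queried transition.
#' @return A `measure_result`.
#' @export
cs_galton <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  w <- pc$weights[[state_index(model$space, cause)]]
  measure_result("galton", cause, effect, w * (1 - w) * (p$s + p$v - 1),
                 intervention = pc$kind)
}

#' @describeIn causal_measures Eells probability-raising difference.
#' @export
cs_eells <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  r <- raw_eells(p$s, p$v)
  measure_result("eells", cause, effect, r$value, r$defined, pc$kind)
}

#' @describeIn causal_measures Suppes probability raising vs. the marginal.
#' @export
cs_suppes <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  r <- raw_suppes(p$s, p$m)
  measure_result("suppes", cause, effect, r$value, r$defined, pc$kind)
}

#' @describeIn causal_measures Cheng causal power.
#' @export
cs_cheng <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  r <- raw_cheng(p$s, p$v)
  measure_result("cheng", cause, effect, r$value, r$defined, pc$kind)
}

#' @describeIn causal_measures Good weight of evidence (bits).
#' @export
cs_good <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  r <- raw_good(p$s, p$v)
  measure_result("good", cause, effect, r$value, r$defined, pc$kind)
}

#' @describeIn causal_measures Lewis normalized relative risk.
#' @export
cs_lewis <- function(model, pc, cause, effect) {
  p <- sv_primitives(model, pc, cause, effect)
  r <- raw_lewis(p$s, p$v)
  measure_result("lewis", cause, effect, r$value, r$defined, pc$kind)
}

#' @describeIn causal_measures Pearl's probability of necessity and
#'   sufficiency (alias of `eells` under exogeneity + monotonicity).
#' @export
pearl_pns <- function(model, pc, cause, effect) {
  r <- cs_eells(model, pc, cause, effect)
  r$measure <- "pearl_pns (eells)"
  r
}

#' @describeIn causal_measures Pearl's probability of necessity (alias of
#'   `lewis`).
#' @export
pearl_pn <- function(model, pc, cause, effect) {
  r <- cs_lewis(model, pc, cause, effect)
  r$measure <- "pearl_pn (lewis)"
  r
}

#' @describeIn causal_measures Pearl's probability of sufficiency (alias of
#'   `cheng`).
#' @export
pearl_ps <- function(model, pc, cause, effect) {
  r <- cs_cheng(model, pc, cause, effect)
  r$measure <- "pearl_ps (cheng)"
  r
}

#' @describeIn causal_measures Lewis closest-possible-world measure: the
#'   counterfactual is the nearest state by Hamming distance; equidistant
#'   minimizers are averaged.
#' @export
cs_lewis_cpw <- function(model, pc = NULL, cause, effect) {
  space <- model$space
  if (!has_bits(space)) {
    stop("lewis_cpw needs binary state labels", call. = FALSE)
  }
  d <- hamming_to_all(space, cause)
  d[state_index(space, cause)] <- NA  # exclude the actual world
  nearest <- which(d == min(d, na.rm = TRUE))
  p_c <- trans_prob(model, cause, effect)
  vals <- lapply(space$labels[nearest], function(nb) {
    raw_ratio_drop(p_c, trans_prob(model, nb, effect))
  })
  defined <- all(vapply(vals, `[[`, logical(1), "defined"))
  if (!defined) {
    value <- NA_real_
  } else {
    v <- vapply(vals, `[[`, numeric(1), "value")
    value <- if (any(v == Inf) && any(v == -Inf)) NA else mean(v)
    defined <- !is.na(value)
  }
  measure_result("lewis_cpw", cause, effect, value, defined,
                 if (is.null(pc)) "closest-world" else pc$kind)
}

#' @describeIn causal_measures Bit-flip perturbation measure: the mean
#'   Hamming distance between the realized effect and the effect distribution
#'   obtained after flipping each cause bit in turn,
#'   `(1/N) sum_i sum_e' P(e'|c[i]) D_H(e, e')`. Needs every single-bit
#'   neighbor of the cause to be a state (full hypercube); no intervention
#'   distribution enters.
#' @export
cs_bit_flip <- function(model, cause, effect) {
  space <- model$space
  if (!has_bits(space)) {
    stop("bit_flip needs binary state labels", call. = FALSE)
  }
  N <- space$bit_width
  d_to_e <- hamming_to_all(space, effect)
  total <- 0
  for (i in seq_len(N)) {
    nb <- flip_bit(cause, i)
    if (!nb %in% space$labels) {
      stop("bit_flip needs the full hypercube: flipped state ", nb,
           " is not in the space", call. = FALSE)
    }
    total <- total + sum(model$matrix[state_index(space, nb), ] * d_to_e)
  }
  measure_result("bit_flip", cause, effect, total / N,
                 intervention = "bit-flip")
}

#' @describeIn causal_measures Effect information `log2(P(e|c)/P(e|C))` in
#'   bits; equals `log2(n) * (det(e,c) - deg(e))`.
#' @export
effect_information <- function(model, pc, cause, effect) {
  s <- sufficiency(model, cause, effect)
  m <- nec_dagger(model, pc, effect)
  r <- raw_ei(s, m)
  measure_result("effect_information", cause, effect, r$value, r$defined,
                 pc$kind)
}

#' @describeIn causal_measures Effective information: the expectation of the
#'   effect information over the joint `P_C(c) P(e|c)`; equals
#'   `log2(n) * (det - deg)`. Expectation-only (no single transition).
#' @export
effective_information <- function(model, pc) {
  check_same_space(model, pc)
  m <- marginal_effect_distribution(model, pc)
  total <- 0
  for (ci in seq_len(model$space$n)) {
    w <- pc$weights[ci]
    if (w == 0) next
    row <- model$matrix[ci, ]
    keep <- row > 0
    total <- total + w * sum(row[keep] * log2(row[keep] / m[keep]))
  }
  measure_result("effective_information", "expectation", "expectation",
                 total, intervention = pc$kind)
}

#' @describeIn causal_measures Effectiveness: effective information
#'   normalized by `log2(n)`, i.e. `det - deg`.
#' @export
effectiveness <- function(model, pc) {
  r <- effective_information(model, pc)
  measure_result("effectiveness", "expectation", "expectation",
                 r$value / log2(model$space$n), r$defined, pc$kind)
}

# --- dispatch and catalogue -------------------------------------------------

#' Catalogue of per-transition measures
#'
#' @param aliases Include Pearl's PN/PS/PNS aliases (default `FALSE`; they
#'   duplicate `lewis`, `cheng`, `eells` exactly).
#' @return Character vector of measure identifiers accepted by
#'   [causal_measure()].
#' @export
measure_catalogue <- function(aliases = FALSE) {
  base <- c("galton", "eells", "suppes", "cheng", "good", "lewis",
            "lewis_cpw", "bit_flip", "effect_information")
  if (aliases) c(base, "pearl_pns", "pearl_pn", "pearl_ps") else base
}

#' Evaluate a measure by name for one transition
#'
#' @param measure Identifier from [measure_catalogue()].
#' @param model A [transition_model()].
#' @param pc An `intervention_distribution` (ignored by `bit_flip`).
#' @param cause,effect State labels.
#' @return A `measure_result`.
#' @export
causal_measure <- function(measure, model, pc, cause, effect) {
  switch(measure,
    galton = cs_galton(model, pc, cause, effect),
    eells = cs_eells(model, pc, cause, effect),
    suppes = cs_suppes(model, pc, cause, effect),
    cheng = cs_cheng(model, pc, cause, effect),
    good = cs_good(model, pc, cause, effect),
    lewis = cs_lewis(model, pc, cause, effect),
    pearl_pns = pearl_pns(model, pc, cause, effect),
    pearl_pn = pearl_pn(model, pc, cause, effect),
    pearl_ps = pearl_ps(model, pc, cause, effect),
    lewis_cpw = cs_lewis_cpw(model, pc, cause, effect),
    bit_flip = cs_bit_flip(model, cause, effect),
    effect_information = effect_information(model, pc, cause, effect),
    stop("unknown measure: ", measure, call. = FALSE)
  )
}
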