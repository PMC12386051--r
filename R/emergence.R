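#' Coarse-graining of a state space
#'
#' A coarse-graining is a total, single-valued map `h` from micro states to
#' macro states (supervenience: the macrostate is fixed by the microstate).
#' Macrostates are ordered by first appearance in the mapping.
#'
#' @param micro_space A [state_space()].
#' @param mapping Character vector of macro labels, either named by micro
#'   label or in the micro space's label order.
#' @return An object of class `coarse_graining` with elements `micro_space`,
#'   `macro_space`, `map` (named micro -> macro), and `macro_codes`
#'   (minimal-width binary codes assigned to macrostates in order, used
#'   whenever a macro-level Hamming structure is required).
#' @export
coarse_graining <- function(micro_space, mapping) {
  if (is.null(names(mapping))) {
    if (length(mapping) != micro_space$n) {
      stop("unnamed mapping must cover every micro state in order",
           call. = FALSE)
    }
    names(mapping) <- micro_space$labels
  }
  missing <- setdiff(micro_space$labels, names(mapping))
  if (length(missing)) {
    stop("mapping is not total; micro state(s) unmapped: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(mapping), micro_space$labels)
  if (length(unknown)) {
    stop("mapping references unknown micro label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    dup <- names(mapping)[duplicated(names(mapping))]
    conflicting <- vapply(unique(dup), function(d) {
      length(unique(mapping[names(mapping) == d])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting macro assignments for micro state(s): ",
           paste(unique(dup)[conflicting], collapse = ", "), call. = FALSE)
    }
    mapping <- mapping[!duplicated(names(mapping))]
  }
  map <- mapping[micro_space$labels]  # micro label order
  macro_labels <- unique(unname(map))  # first-appearance order
  if (length(macro_labels) < 2) {
    stop("a coarse-graining needs at least 2 macrostates", call. = FALSE)
  }
  width <- max(1L, ceiling(log2(length(macro_labels))))
  codes <- stats::setNames(int_to_bits(seq_along(macro_labels) - 1L, width),
                           macro_labels)
  structure(
    list(micro_space = micro_space,
         macro_space = state_space(macro_labels),
         map = map, macro_codes = codes),
    class = "coarse_graining"
  )
}

#' @export
print.coarse_graining <- function(x, ...) {
  cat("Coarse-graining:", x$micro_space$n, "micro states ->",
      x$macro_space$n, "macrostates\n")
  for (m in x$macro_space$labels) {
    members <- names(x$map)[x$map == m]
    cat("  ", m, " <- {", paste(utils::head(members, 10L), collapse = ", "),
        if (length(members) > 10L) ", ..." else "", "}\n", sep = "")
  }
  invisible(x)
}

#' Coarse-grain a transition model
#'
#' Aggregates the micro TPM onto the macrostates:
#' `P_macro(y|x) = sum_{c in h^-1(x)} w_x(c) sum_{e in h^-1(y)} P(e|c)`,
#' where `w_x` are per-macrostate aggregation weights over the micro members.
#'
#' @param model A micro-level [transition_model()].
#' @param cg A [coarse_graining()] over the model's space.
#' @param weights `NULL` for uniform weights within each macrostate
#'   (default), or an `intervention_distribution` over the micro space whose
#'   weights are restricted and renormalized within each macrostate
#'   (macrostates carrying zero total mass fall back to uniform).
#' @return A [transition_model()] over the macro space.
#' @export
coarse_grain <- function(model, cg, weights = NULL) {
  if (!identical(model$space$labels, cg$micro_space$labels)) {
    stop("coarse-graining and model are over different micro spaces",
         call. = FALSE)
  }
  micro_w <- if (is.null(weights)) {
    rep(1, model$space$n)
  } else {
    check_same_space(model, weights)
    weights$weights
  }
  macro_labels <- cg$macro_space$labels
  k <- length(macro_labels)
  macro <- matrix(0, k, k, dimnames = list(macro_labels, macro_labels))
  group <- factor(cg$map, levels = macro_labels)
  for (x in seq_len(k)) {
    members <- which(group == macro_labels[x])
    w <- micro_w[members]
    if (sum(w) == 0) w <- rep(1, length(members))
    w <- w / sum(w)
    aggregated <- as.numeric(w %*% model$matrix[members, , drop = FALSE])
    macro[x, ] <- tapply(aggregated, group, sum)
  }
  transition_model(macro, cg$macro_space)
}

# Relabel a macro model with its binary codes so that Hamming-based
# operations (local interventions, lewis_cpw, bit_flip) are defined at the
# macroscale. Codes are minimal-width and assigned in macrostate order.
recode_binary <- function(model, codes = NULL) {
  if (has_bits(model$space)) return(model)
  labels <- model$space$labels
  if (is.null(codes)) {
    width <- max(1L, ceiling(log2(length(labels))))
    codes <- stats::setNames(int_to_bits(seq_along(labels) - 1L, width),
                             labels)
  }
  m <- model$matrix
  dimnames(m) <- list(unname(codes[labels]), unname(codes[labels]))
  transition_model(m, state_space(unname(codes[labels])))
}

#' Intervention distribution at the macroscale
#'
#' `maxent` and `observational` are computed directly on the macro model.
#' `local` uses the macrostates' binary codes; with two macrostates and
#' `delta >= 1` the Hamming ball covers the whole space, so the local
#' distribution degenerates to maxent (as it must: a two-state macro space
#' has no non-trivial neighborhood structure).
#'
#' @param kind `"maxent"`, `"observational"`, or `"local"`.
#' @param macro_model A macro-level [transition_model()].
#' @param center Macro state label (required for `"local"`).
#' @param delta Hamming radius for `"local"` (default 1).
#' @param codes Optional named binary codes for the macro labels (defaults
#'   to minimal-width codes in label order).
#' @return An `intervention_distribution` over the macro space.
#' @export
macro_intervention <- function(kind, macro_model, center = NULL, delta = 1,
                               codes = NULL) {
  kind <- match.arg(kind, c("maxent", "observational", "local"))
  if (kind == "maxent") return(maxent_distribution(macro_model$space))
  if (kind == "observational") return(observational_distribution(macro_model))
  if (is.null(center)) stop("local macro intervention needs a center state",
                            call. = FALSE)
  coded <- recode_binary(macro_model, codes)
  idx <- state_index(macro_model$space, center)
  dist <- local_distribution(coded$space, coded$space$labels[idx], delta)
  new_intervention(macro_model$space, dist$weights, "local",
                   params = dist$params)
}

combine_ce <- function(macro, micro) {
  if (!macro$defined || !micro$defined) {
    return(list(value = NA_real_, defined = FALSE))
  }
  a <- macro$value; b <- micro$value
  if (is.infinite(a) && is.infinite(b)) {
    if (a == b) return(list(value = NA_real_, defined = FALSE))
    return(list(value = a, defined = TRUE))
  }
  list(value = a - b, defined = TRUE)  # -Inf micro, finite macro => +Inf
}

ce_direction <- function(value, defined) {
  if (!defined || is.na(value)) return(NA_character_)
  if (value > 0) "emergence" else if (value < 0) "reduction" else "neutral"
}

#' Causal emergence of a coarse-graining
#'
#' Computes `CE = CS_macro - CS_micro` for a chosen measure: the measure is
#' evaluated on the micro model for a micro transition (or in expectation)
#' and on the coarse-grained macro model for the macro image of that
#' transition (or in expectation), and the difference is reported. Positive
#' CE is causal emergence, negative CE causal reduction. A `-Inf` micro value
#' against a finite macro value yields `+Inf` ("infinite causal emergence",
#' e.g. a preventive micro cause whose macro image is a positive cause).
#'
#' The bit-flip measure is the one catalogue entry whose raw value is
#' denominated in label bits, which differ between scales; for cross-scale
#' comparison its value at each scale is normalized by that scale's label
#' width (mean per-bit displacement).
#'
#' @param measure Identifier from [measure_catalogue()].
#' @param micro A micro-level [transition_model()].
#' @param cg A [coarse_graining()] of the micro space.
#' @param cause,effect Micro state labels, or `NULL` with
#'   `scope = "expectation"`.
#' @param scope `"transition"` or `"expectation"`.
#' @param intervention Micro-level intervention: an
#'   `intervention_distribution` or a kind string (see
#'   [resolve_intervention()]).
#' @param macro_kind Macro-level intervention kind; defaults to the micro
#'   kind (scales are paired by tag).
#' @param delta Radius for local interventions (both scales).
#' @param weights Expectation weighting (see [cs_expectation()]).
#' @return A one-row data frame (`emergence_report`): measure, scope,
#'   micro/macro transition, `cs_micro`, `cs_macro`, `ce`, `defined`,
#'   `direction`, and the intervention kinds at each scale.
#' @export
causal_emergence <- function(measure, micro, cg, cause = NULL, effect = NULL,
                             scope = c("transition", "expectation"),
                             intervention = "maxent", macro_kind = NULL,
                             delta = 1, weights = "stationary") {
  scope <- match.arg(scope)
  iv <- resolve_intervention(micro, intervention, delta)
  if (is.null(macro_kind)) {
    macro_kind <- if (iv$kind %in% c("maxent", "observational", "local")) {
      iv$kind
    } else "maxent"
  }
  macro <- coarse_grain(micro, cg, weights = iv$dist)
  # all macro-scale computation runs on the binary-coded relabeling so that
  # local interventions and Hamming-based measures are defined there
  mc <- recode_binary(macro, cg$macro_codes)
  code <- function(lbl) cg$macro_codes[[lbl]]

  if (scope == "transition") {
    if (is.null(cause) || is.null(effect)) {
      stop("transition scope needs cause and effect labels", call. = FALSE)
    }
    macro_cause <- cg$map[[cause]]
    macro_effect <- cg$map[[effect]]
    if (measure == "bit_flip") {
      micro_res <- cs_bit_flip(micro, cause, effect)
      micro_res$value <- micro_res$value / micro$space$bit_width
      macro_res <- cs_bit_flip(mc, code(macro_cause), code(macro_effect))
      macro_res$value <- macro_res$value / mc$space$bit_width
    } else {
      micro_res <- causal_measure(measure, micro, iv$for_cause(cause),
                                  cause, effect)
      macro_pc <- switch(macro_kind,
        local = local_distribution(mc$space, code(macro_cause), delta),
        maxent = maxent_distribution(mc$space),
        observational = observational_distribution(mc)
      )
      macro_res <- causal_measure(measure, mc, macro_pc,
                                  code(macro_cause), code(macro_effect))
    }
  } else {
    macro_cause <- macro_effect <- cause <- effect <- "expectation"
    micro_res <- cs_expectation(measure, micro, intervention,
                                weights = weights, delta = delta)
    macro_res <- cs_expectation(measure, mc, macro_kind,
                                weights = weights, delta = delta)
    if (measure == "bit_flip") {
      micro_res$value <- micro_res$value / micro$space$bit_width
      macro_res$value <- macro_res$value / mc$space$bit_width
    }
  }

  ce <- combine_ce(macro_res, micro_res)
  out <- data.frame(
    measure = measure, scope = scope,
    cause = cause, effect = effect,
    macro_cause = macro_cause, macro_effect = macro_effect,
    cs_micro = micro_res$value, cs_macro = macro_res$value,
    ce = ce$value, defined = ce$defined,
    direction = ce_direction(ce$value, ce$defined),
    micro_intervention = iv$kind, macro_intervention = macro_kind,
    stringsAsFactors = FALSE
  )
  class(out) <- c("emergence_report", class(out))
  out
}

#' Supervenience / consistency check of a coarse-graining
#'
#' Verifies that the mapping is total and single-valued (guaranteed by
#' [coarse_graining()]) and measures, for each macrostate, how much its micro
#' members disagree once their rows are aggregated to the macro level. A zero
#' residual means every micro realization of a macrostate induces the same
#' macro dynamics (the coarse-graining is dynamically consistent whatever the
#' aggregation weights), as holds for the bipartite family by construction.
#'
#' @param model A micro [transition_model()].
#' @param cg A [coarse_graining()].
#' @param tolerance Residual threshold for the `consistent` flag.
#' @return A list with `consistent` (logical) and `residual` (max absolute
#'   disagreement between aggregated member rows).
#' @export
supervenience_check <- function(model, cg, tolerance = 1e-9) {
  macro_labels <- cg$macro_space$labels
  group <- factor(cg$map, levels = macro_labels)
  # each micro row aggregated over effect groups
  agg <- t(apply(model$matrix, 1L, function(r) tapply(r, group, sum)))
  residual <- 0
  for (x in macro_labels) {
    members <- which(group == x)
    if (length(members) < 2) next
    rows <- agg[members, , drop = FALSE]
    spread <- apply(rows, 2L, function(col) diff(range(col)))
    residual <- max(residual, max(spread))
  }
  list(consistent = residual <= tolerance, residual = residual)
}
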