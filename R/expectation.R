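# Expectation of per-transition measures over the joint P(c,e) = P_w(c) P(e|c).
#
# Two conventions interact here:
#  * generically, zero-probability transitions contribute nothing and are
#    skipped (their per-transition value may be -Inf or undefined, but it is
#    weighted by zero);
#  * for the ratio measures lewis / pearl_pn, the weighted term
#    P(c,e) * (s + v - 1)/s cancels exactly to P_w(c) [P(e|c) - P(e|C\c)],
#    which is also the continuous limit of weight x value as P(e|c) -> 0.
#    Summed over effects this gives the analytic identity E[lewis] = 0 for
#    every TPM and every intervention distribution -- the behavior the
#    measure is known for (its average carries no information).
#
# Undefined included terms make the whole expectation undefined; included
# +Inf and -Inf terms coexisting do as well, otherwise infinities propagate.

#' Resolve an intervention specification
#'
#' Accepts either a ready-made `intervention_distribution` or a kind string:
#' `"maxent"`, `"observational"`, or `"local"`. Local interventions are
#' cause-centered, so for `"local"` the result carries a generator closure
#' mapping each cause label to the Hamming ball around it.
#'
#' @param model A [transition_model()].
#' @param intervention An `intervention_distribution` or one of `"maxent"`,
#'   `"observational"`, `"local"`.
#' @param delta Radius for local interventions (default 1).
#' @return A list with `kind`, and either `dist` (shared distribution, `NULL`
#'   for cause-centered local) or `for_cause(cause)` (per-cause generator).
#' @export
resolve_intervention <- function(model, intervention, delta = 1) {
  if (inherits(intervention, "intervention_distribution")) {
    check_same_space(model, intervention)
    return(list(kind = intervention$kind, dist = intervention,
                for_cause = function(cause) intervention))
  }
  kind <- match.arg(intervention, c("maxent", "observational", "local"))
  if (kind == "local") {
    space <- model$space
    cache <- new.env(parent = emptyenv())
    return(list(kind = "local", dist = NULL, for_cause = function(cause) {
      if (is.null(cache[[cause]])) {
        cache[[cause]] <- local_distribution(space, cause, delta)
      }
      cache[[cause]]
    }))
  }
  dist <- if (kind == "maxent") maxent_distribution(model$space)
          else observational_distribution(model)
  list(kind = kind, dist = dist, for_cause = function(cause) dist)
}

resolve_weights <- function(model, weights, intervention_resolved) {
  if (is.numeric(weights)) {
    w <- custom_distribution(model$space, weights)$weights
    return(list(w = w, source = "custom"))
  }
  weights <- match.arg(weights, c("stationary", "intervention"))
  if (weights == "stationary") {
    return(list(w = observational_distribution(model)$weights,
                source = "stationary"))
  }
  if (is.null(intervention_resolved$dist)) {
    stop("weights = \"intervention\" is not defined for cause-centered ",
         "local interventions; use \"stationary\" or a custom vector",
         call. = FALSE)
  }
  list(w = intervention_resolved$dist$weights, source = "intervention")
}

# Per-cause vector of measure values over all effects; list(value=, defined=)
# of vectors. s = TPM row, v = 1 - P(e|C\c), m = P(e|C), all over effects.
measure_row_values <- function(measure, model, pc, ci) {
  n <- model$space$n
  labels <- model$space$labels
  s <- model$matrix[ci, ]
  defined <- rep(TRUE, n)
  if (measure %in% c("eells", "pearl_pns", "cheng", "pearl_ps", "good",
                     "galton")) {
    v <- 1 - counterfactual_effect_distribution(model, pc, labels[ci])
  }
  value <- switch(measure,
    eells = , pearl_pns = s + v - 1,
    galton = {
      w <- pc$weights[ci]
      w * (1 - w) * (s + v - 1)
    },
    suppes = s - marginal_effect_distribution(model, pc),
    cheng = , pearl_ps = {
      out <- ifelse(v == 0, NA_real_, (s + v - 1) / v)
      defined <- v != 0
      out
    },
    good = {
      out <- numeric(n)
      und <- s == 1 & v == 0
      out[s == 1 & v > 0] <- Inf
      out[s < 1 & v == 0] <- -Inf
      ok <- s < 1 & v > 0
      out[ok] <- log2(v[ok] / (1 - s[ok]))
      out[und] <- NA_real_
      defined <- !und
      out
    },
    effect_information = {
      m <- marginal_effect_distribution(model, pc)
      out <- numeric(n)
      und <- s == 0 & m == 0
      out[s == 0 & m > 0] <- -Inf
      out[s > 0 & m == 0] <- Inf
      ok <- s > 0 & m > 0
      out[ok] <- log2(s[ok] / m[ok])
      out[und] <- NA_real_
      defined <- !und
      out
    },
    lewis_cpw = {
      d <- hamming_to_all(model$space, labels[ci])
      d[ci] <- NA
      nearest <- which(d == min(d, na.rm = TRUE))
      acc <- numeric(n)
      und <- rep(FALSE, n)
      for (nb in nearest) {
        p_alt <- model$matrix[nb, ]
        term <- ifelse(s > 0, (s - p_alt) / s,
                       ifelse(p_alt > 0, -Inf, NA_real_))
        und <- und | is.na(term)
        acc <- acc + term / length(nearest)
      }
      defined <- !und & !is.nan(acc)
      acc[!defined] <- NA_real_
      acc
    },
    bit_flip = {
      N <- model$space$bit_width
      if (is.na(N)) stop("bit_flip needs binary labels", call. = FALSE)
      D <- vapply(labels, function(e) hamming_to_all(model$space, e),
                  numeric(n))  # D[e', e]
      avg <- numeric(n)
      for (i in seq_len(N)) {
        nb <- flip_bit(labels[ci], i)
        avg <- avg + model$matrix[state_index(model$space, nb), ] / N
      }
      as.numeric(avg %*% D)
    },
    stop("unknown measure: ", measure, call. = FALSE)
  )
  list(value = value, defined = defined)
}

#' Expectation of a per-transition measure
#'
#' Computes `sum_{c,e} P(c,e) CS(e,c)` with `P(c,e) = P_w(c) P(e|c)`. The
#' cause weighting defaults to the stationary distribution of the chain; the
#' intervention distribution entering each per-transition value may be any
#' kind, including cause-centered local interventions. Zero-probability
#' transitions contribute nothing; for the `lewis` ratio (and its `pearl_pn`
#' alias) the weighted terms cancel analytically, making the expectation
#' identically zero.
#'
#' @param measure Identifier from [measure_catalogue()].
#' @param model A [transition_model()].
#' @param intervention See [resolve_intervention()].
#' @param weights `"stationary"` (default), `"intervention"`, or a custom
#'   probability vector over causes.
#' @param delta Radius for local interventions.
#' @return A `measure_result` with `cause = effect = "expectation"`.
#' @export
cs_expectation <- function(measure, model, intervention = "maxent",
                           weights = "stationary", delta = 1) {
  iv <- resolve_intervention(model, intervention, delta)
  wres <- resolve_weights(model, weights, iv)
  w <- wres$w
  labels <- model$space$labels
  n <- model$space$n

  total <- 0
  any_pos_inf <- FALSE
  any_neg_inf <- FALSE
  undefined <- FALSE

  for (ci in seq_len(n)) {
    if (w[ci] == 0) next
    pc <- iv$for_cause(labels[ci])
    row <- model$matrix[ci, ]
    if (measure %in% c("lewis", "pearl_pn")) {
      # cancelled form over all effects: P_w(c) [sum_e P(e|c) - sum_e P(e|C\c)]
      cf <- counterfactual_effect_distribution(model, pc, labels[ci])
      total <- total + w[ci] * (sum(row) - sum(cf))
      next
    }
    mv <- measure_row_values(measure, model, pc, ci)
    active <- row > 0
    if (any(active & !mv$defined)) { undefined <- TRUE; break }
    vals <- mv$value[active]
    joint <- w[ci] * row[active]
    any_pos_inf <- any_pos_inf || any(vals == Inf)
    any_neg_inf <- any_neg_inf || any(vals == -Inf)
    fin <- is.finite(vals)
    total <- total + sum(joint[fin] * vals[fin])
  }

  if (undefined || (any_pos_inf && any_neg_inf)) {
    return(measure_result(measure, "expectation", "expectation", NA_real_,
                          defined = FALSE, intervention = iv$kind))
  }
  value <- if (any_pos_inf) Inf else if (any_neg_inf) -Inf else total
  res <- measure_result(measure, "expectation", "expectation", value,
                        intervention = iv$kind)
  res$weight_source <- wres$source
  res
}
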