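#' Parameter sweep of causal emergence over the bipartite model
#'
#' Evaluates causal emergence for a set of measures on a lattice of
#' (dilution, rewiring) parameters of the bipartite model, for the
#' reference cause's main transition, its secondary transition, and/or the
#' expectation over all transitions. This is the tabular counterpart of the
#' determinism-by-degeneracy heatmaps: one long-format row per
#' measure x grid point x scope.
#'
#' At `dilution = 0` all transitions from a cause tie, so "main" and
#' "secondary" are taken as the d -> 0 limit of the generator's target map
#' (the rewired main target, and the first other opposite-group state).
#'
#' @param measures Character vector of measure identifiers (default: the
#'   full per-transition catalogue).
#' @param dilution,rewiring Numeric grids (default `seq(0, 1, 0.1)`,
#'   an 11 x 11 lattice).
#' @param n_a,n_b Bipartite group sizes (default 8, 8).
#' @param scopes Subset of `c("main", "secondary", "expectation")`.
#' @param intervention Micro intervention kind (`"local"`, `"maxent"`,
#'   `"observational"`); macro interventions are paired by tag.
#' @param delta Radius for local interventions.
#' @param cause Reference cause for the main/secondary scopes (default: the
#'   first group-A state).
#' @param weights Expectation weighting (see [cs_expectation()]).
#' @return A data frame with columns `measure`, `dilution`, `rewiring`,
#'   `scope`, plus the [causal_emergence()] report columns (`cs_micro`,
#'   `cs_macro`, `ce`, `defined`, `direction`, intervention kinds).
#' @export
ce_sweep <- function(measures = measure_catalogue(),
                     dilution = seq(0, 1, 0.1),
                     rewiring = seq(0, 1, 0.1),
                     n_a = 8, n_b = 8,
                     scopes = c("main", "secondary", "expectation"),
                     intervention = "local", delta = 1,
                     cause = NULL, weights = "stationary") {
  scopes <- match.arg(scopes, c("main", "secondary", "expectation"),
                      several.ok = TRUE)
  rows <- vector("list", 0L)
  for (d in dilution) {
    for (g in rewiring) {
      model <- bipartite_model(n_a, n_b, dilution = d, rewiring = g)
      cg <- bipartite_macro_mapping(model)
      groups <- attr(model, "groups")
      ref <- if (is.null(cause)) groups$A[1L] else cause
      main_eff <- attr(model, "main_map")[[ref]]
      opp <- if (ref %in% groups$A) groups$B else groups$A
      sec_eff <- opp[opp != main_eff][1L]
      for (measure in measures) {
        for (scope in scopes) {
          rep_ <- switch(scope,
            main = causal_emergence(measure, model, cg, ref, main_eff,
                                    scope = "transition",
                                    intervention = intervention,
                                    delta = delta),
            secondary = causal_emergence(measure, model, cg, ref, sec_eff,
                                         scope = "transition",
                                         intervention = intervention,
                                         delta = delta),
            expectation = causal_emergence(measure, model, cg,
                                           scope = "expectation",
                                           intervention = intervention,
                                           delta = delta, weights = weights)
          )
          rep_$scope <- scope
          rep_ <- cbind(data.frame(dilution = d, rewiring = g), rep_)
          rows[[length(rows) + 1L]] <- rep_
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Cross-measure normalized average of causal emergence
#'
#' Normalizes each measure's CE values by the measure's maximum absolute
#' finite CE over the supplied table (so each measure ranges within
#' [-1, 1]), then averages across measures at each grid point. Non-finite or
#' undefined cells are excluded from the average. This is the standard way
#' to combine measures with incommensurable units into a single
#' emergence map.
#'
#' @param sweep_table Output of [ce_sweep()] (typically filtered to one
#'   scope).
#' @return A data frame with columns `dilution`, `rewiring`,
#'   `mean_normalized_ce`, and `n_measures` (count entering each cell).
#' @export
normalized_average_ce <- function(sweep_table) {
  tab <- sweep_table
  tab$norm_ce <- NA_real_
  for (m in unique(tab$measure)) {
    sel <- tab$measure == m
    finite <- sel & tab$defined & is.finite(tab$ce)
    peak <- suppressWarnings(max(abs(tab$ce[finite])))
    if (!is.finite(peak) || peak == 0) peak <- 1
    tab$norm_ce[finite] <- tab$ce[finite] / peak
  }
  agg <- stats::aggregate(
    norm_ce ~ dilution + rewiring, data = tab,
    FUN = function(x) c(mean = mean(x, na.rm = TRUE), n = sum(!is.na(x))),
    na.action = stats::na.pass
  )
  data.frame(
    dilution = agg$dilution, rewiring = agg$rewiring,
    mean_normalized_ce = agg$norm_ce[, "mean"],
    n_measures = agg$norm_ce[, "n"]
  )
}
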