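#' Read a transition model from CSV
#'
#' Expected layout: header row of state labels (effect order), first column
#' of state labels (cause order), probability cells with `.` as the decimal
#' separator. Cause and effect label sets must agree.
#'
#' @param path CSV file path.
#' @param tolerance Row-sum tolerance passed to [transition_model()].
#' @return A [transition_model()] with labels in file order.
#' @examples
#' read_tpm(system.file("extdata", "light_switch_tpm.csv",
#'                      package = "causalem"))
#' @export
read_tpm <- function(path, tolerance = 1e-9) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  labels <- as.character(raw[[1L]])
  effects <- colnames(raw)[-1L]
  if (anyDuplicated(labels) || anyDuplicated(effects)) {
    stop("duplicate state labels in ", path, call. = FALSE)
  }
  if (!setequal(labels, effects)) {
    stop("cause and effect label sets disagree in ", path, call. = FALSE)
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  m <- m[, labels, drop = FALSE]  # align effect order to cause order
  rownames(m) <- labels
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tolerance)
  if (length(bad)) {
    stop("row for state '", labels[bad[1L]], "' sums to ",
         format(rs[bad[1L]]), ", not 1", call. = FALSE)
  }
  transition_model(m, state_space(labels), tolerance = tolerance)
}

#' Write a transition model to CSV
#'
#' @param model A [transition_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm <- function(model, path) {
  df <- data.frame(state = model$space$labels, model$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a micro-to-macro mapping from CSV
#'
#' Two columns, `micro_state, macro_state`. Macrostates are ordered by first
#' appearance. Duplicate micro keys with conflicting macro values are
#' rejected.
#'
#' @param path CSV file path.
#' @param micro_space Optional [state_space()] to validate against (and to
#'   supply binary structure); defaults to a space built from the file's
#'   micro labels.
#' @return A [coarse_graining()].
#' @export
read_mapping <- function(path, micro_space = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("mapping file needs two columns", call. = FALSE)
  map <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (is.null(micro_space)) {
    micro_space <- state_space(unique(names(map)))
  }
  coarse_graining(micro_space, map)
}

#' Write a coarse-graining mapping to CSV
#'
#' @param cg A [coarse_graining()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(cg, path) {
  utils::write.csv(
    data.frame(micro_state = names(cg$map), macro_state = unname(cg$map)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a custom intervention distribution from CSV
#'
#' Two columns, `state, weight`.
#'
#' @param path CSV file path.
#' @param space A [state_space()].
#' @return An `intervention_distribution` of kind `"custom"`.
#' @export
read_intervention <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  custom_distribution(space, stats::setNames(as.numeric(df[[2L]]),
                                             as.character(df[[1L]])))
}

#' Long-format table of measure values
#'
#' Evaluates a set of measures on a set of transitions (by default every
#' positive-probability transition plus each measure's expectation) and
#' returns one row per measure x transition.
#'
#' @param model A [transition_model()].
#' @param intervention See [resolve_intervention()].
#' @param measures Measure identifiers (default: full catalogue).
#' @param transitions `NULL` for all transitions with `P(e|c) > 0`, or a
#'   two-column data frame / matrix of (cause, effect) label pairs.
#' @param expectation Include expectation rows (default `TRUE`).
#' @param delta Local-intervention radius.
#' @param weights Expectation weighting.
#' @return Data frame with columns `measure`, `cause`, `effect`,
#'   `intervention_kind`, `value`, `defined`.
#' @export
measures_table <- function(model, intervention = "maxent",
                           measures = measure_catalogue(),
                           transitions = NULL, expectation = TRUE,
                           delta = 1, weights = "stationary") {
  iv <- resolve_intervention(model, intervention, delta)
  if (is.null(transitions)) {
    idx <- which(model$matrix > 0, arr.ind = TRUE)
    transitions <- data.frame(
      cause = model$space$labels[idx[, 1L]],
      effect = model$space$labels[idx[, 2L]],
      stringsAsFactors = FALSE
    )
    transitions <- transitions[order(transitions$cause, transitions$effect), ]
  } else {
    transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
    names(transitions)[1:2] <- c("cause", "effect")
  }
  rows <- list()
  for (m in measures) {
    for (k in seq_len(nrow(transitions))) {
      cause <- transitions$cause[k]
      effect <- transitions$effect[k]
      res <- causal_measure(m, model, iv$for_cause(cause), cause, effect)
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
    if (expectation) {
      res <- cs_expectation(m, model, intervention, weights = weights,
                            delta = delta)
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Serialize value columns: infinities become "inf"/"-inf", undefined cells
# are left empty (the `defined` column disambiguates).
format_value_column <- function(x, defined = NULL) {
  out <- vapply(seq_along(x), function(i) {
    v <- x[i]
    if (!is.null(defined) && !defined[i]) return("")
    if (is.na(v)) return("")
    if (v == Inf) return("inf")
    if (v == -Inf) return("-inf")
    format(v, digits = 15)
  }, character(1))
  out
}

#' Write a results table to CSV with stable serialization
#'
#' @param table Data frame with a `value` (or `ce`/`cs_micro`/`cs_macro`)
#'   column and optionally a `defined` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  tab <- table
  def <- if ("defined" %in% names(tab)) tab$defined else NULL
  for (col in intersect(c("value", "ce", "cs_micro", "cs_macro"),
                        names(tab))) {
    tab[[col]] <- format_value_column(tab[[col]], def)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
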