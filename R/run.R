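# Config-driven pipeline: the programmatic core behind the command-line
# interface. A run config is a named list (from YAML or JSON) with a `task`
# plus task-specific fields; unknown keys are rejected so typos fail loudly.

config_keys <- list(
  generate = c("task", "model", "out_tpm", "out_mapping"),
  measures = c("task", "model", "tpm", "measures", "intervention", "delta",
               "cause", "effect", "weights", "out"),
  emergence = c("task", "model", "tpm", "mapping", "measures",
                "intervention", "delta", "scope", "cause", "effect",
                "weights", "out"),
  sweep = c("task", "measures", "dilution", "rewiring", "n_a", "n_b",
            "scopes", "intervention", "delta", "weights", "out")
)

#' Read a run configuration (YAML or JSON)
#'
#' @param path Config file; `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return A validated named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list.
#' @export
validate_run_config <- function(cfg) {
  task <- cfg$task
  if (is.null(task) || !task %in% names(config_keys)) {
    stop("config must set task to one of: ",
         paste(names(config_keys), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(cfg), config_keys[[task]])
  if (length(unknown)) {
    stop("unknown config key(s) for task '", task, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

build_model_from_recipe <- function(recipe) {
  kind <- match.arg(recipe$model, c("bipartite", "nand"))
  if (kind == "bipartite") {
    bipartite_model(
      n_a = recipe$n_a %||% 8, n_b = recipe$n_b %||% 8,
      dilution = recipe$dilution, rewiring = recipe$rewiring
    )
  } else {
    nand_model(recipe$n_nodes, recipe$noise)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_config_model <- function(cfg) {
  if (!is.null(cfg$model)) {
    model <- build_model_from_recipe(cfg$model)
    cg <- if (identical(cfg$model$model, "nand")) nand_macro_mapping(model)
          else bipartite_macro_mapping(model)
    list(model = model, cg = cg)
  } else if (!is.null(cfg$tpm)) {
    model <- read_tpm(cfg$tpm)
    cg <- if (!is.null(cfg$mapping)) read_mapping(cfg$mapping, model$space)
          else NULL
    list(model = model, cg = cg)
  } else {
    stop("config needs either a model recipe or a tpm path", call. = FALSE)
  }
}

#' Execute a run configuration
#'
#' Dispatches on `config$task` (`generate`, `measures`, `emergence`,
#' `sweep`), writes the task's output CSV(s) plus a JSON manifest echoing
#' the config, and returns the main result invisibly. Identical configs
#' produce identical outputs: nothing in the pipeline is randomized.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param manifest Write a `<out>.manifest.json` next to the main output
#'   (default `TRUE`).
#' @return The main result object, invisibly.
#' @export
run <- function(config, manifest = TRUE) {
  cfg <- validate_run_config(config)
  result <- switch(cfg$task,
    generate = {
      parts <- resolve_config_model(cfg)
      if (!is.null(cfg$out_tpm)) write_tpm(parts$model, cfg$out_tpm)
      if (!is.null(cfg$out_mapping) && !is.null(parts$cg)) {
        write_mapping(parts$cg, cfg$out_mapping)
      }
      parts$model
    },
    measures = {
      parts <- resolve_config_model(cfg)
      transitions <- if (!is.null(cfg$cause)) {
        data.frame(cause = cfg$cause, effect = cfg$effect)
      } else NULL
      tab <- measures_table(
        parts$model, intervention = cfg$intervention %||% "maxent",
        measures = cfg$measures %||% measure_catalogue(),
        transitions = transitions, delta = cfg$delta %||% 1,
        weights = cfg$weights %||% "stationary"
      )
      if (!is.null(cfg$out)) write_results(tab, cfg$out)
      tab
    },
    emergence = {
      parts <- resolve_config_model(cfg)
      if (is.null(parts$cg)) {
        stop("emergence task needs a mapping (or a model recipe with a ",
             "built-in coarse-graining)", call. = FALSE)
      }
      measures <- cfg$measures %||% measure_catalogue()
      scope <- cfg$scope %||% "transition"
      rows <- lapply(measures, function(m) {
        causal_emergence(
          m, parts$model, parts$cg, cause = cfg$cause, effect = cfg$effect,
          scope = scope, intervention = cfg$intervention %||% "maxent",
          delta = cfg$delta %||% 1, weights = cfg$weights %||% "stationary"
        )
      })
      tab <- do.call(rbind, rows)
      if (!is.null(cfg$out)) write_results(tab, cfg$out)
      tab
    },
    sweep = {
      tab <- ce_sweep(
        measures = cfg$measures %||% measure_catalogue(),
        dilution = cfg$dilution %||% seq(0, 1, 0.1),
        rewiring = cfg$rewiring %||% seq(0, 1, 0.1),
        n_a = cfg$n_a %||% 8, n_b = cfg$n_b %||% 8,
        scopes = cfg$scopes %||% c("main", "secondary", "expectation"),
        intervention = cfg$intervention %||% "local",
        delta = cfg$delta %||% 1,
        weights = cfg$weights %||% "stationary"
      )
      if (!is.null(cfg$out)) write_results(tab, cfg$out)
      tab
    }
  )
  if (manifest) {
    out <- cfg$out %||% cfg$out_tpm
    if (!is.null(out)) {
      jsonlite::write_json(
        list(config = unclass(cfg),
             package = "causalem",
             version = as.character(utils::packageVersion("causalem")),
             deterministic = TRUE,
             stationary_tolerance = 1e-12),
        paste0(out, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE
      )
    }
  }
  invisible(result)
}
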