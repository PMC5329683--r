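# YAML config schema: every parameter is a {value, unit} pair and units are
# validated against the canonical table, never guessed. Unknown keys are
# rejected with their path.

quantity_out <- function(value, unit) list(value = value, unit = unit)

quantity_in <- function(x, key, path) {
  if (!is.list(x) || !setequal(names(x), c("value", "unit"))) {
    abort_config(sprintf("`%s` must be a {value, unit} pair", path),
                 field = path)
  }
  want <- config_units()[[key]]
  if (!identical(as.character(x$unit), want)) {
    abort_config(sprintf("`%s` has unit '%s'; expected '%s'",
                         path, x$unit, want), field = path)
  }
  as.numeric(x$value)
}

section_in <- function(sec, keys, path, defaults) {
  unknown <- setdiff(names(sec), keys)
  if (length(unknown)) {
    abort_config(sprintf("unknown key(s) under `%s`: %s", path,
                         paste(unknown, collapse = ", ")),
                 field = paste0(path, ".", unknown[1])) # nolint
  }
  out <- defaults
  for (nm in names(sec)) {
    out[[nm]] <- quantity_in(sec[[nm]], nm, paste0(path, ".", nm))
  }
  out
}

#' Write a model configuration to YAML
#'
#' Serialises an [island_config()] to a human-readable YAML file in which
#' every parameter carries an explicit unit string. [read_island_config()]
#' validates those units on the way back in; load -> dump -> load is the
#' identity.
#'
#' @param config an [island_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_island_config <- function(config, path) {
  stopifnot(inherits(config, "island_config"))
  u <- config_units()
  pack <- function(lst) {
    stats::setNames(
      lapply(names(lst), function(nm) quantity_out(lst[[nm]], u[[nm]])),
      names(lst))
  }
  doc <- list(
    name = config$name,
    horizon = quantity_out(config$horizon, "yr"),
    dt = quantity_out(config$dt, "yr"),
    temp_mode = config$temp_mode,
    forcings = pack(unclass(config$forcings)),
    profile = pack(unclass(config$profile)),
    params = pack(unclass(config$params)),
    init = as.list(unclass(config$init)),
    flux_scale = as.list(config$flux_scale),
    extra_sinks = if (nrow(config$extra_sinks)) {
      lapply(seq_len(nrow(config$extra_sinks)),
             function(i) as.list(config$extra_sinks[i, ]))
    } else {
      list()
    }
  )
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' Read and validate a model configuration from YAML
#'
#' Loads a configuration written in the package's YAML schema: each
#' parameter a `{value, unit}` pair with the unit checked against the
#' canonical unit table, unknown keys rejected with their path, and all
#' structural invariants (stay-duration fractions summing to 1,
#' non-negative stocks, ...) re-validated. Omitted parameters take their
#' published default.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [island_config()].
#' @export
#' @examples
#' f <- system.file("extdata", "as_printed.yaml", package = "islandcarbon")
#' read_island_config(f)
read_island_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("config file not found: ", path), field = "path")
  }
  doc <- yaml::read_yaml(path)
  top <- c("name", "horizon", "dt", "temp_mode", "forcings", "profile",
           "params", "init", "flux_scale", "extra_sinks")
  unknown <- setdiff(names(doc), top)
  if (length(unknown)) {
    abort_config(paste("unknown top-level key(s):",
                       paste(unknown, collapse = ", ")), field = unknown[1])
  }
  forc <- section_in(doc$forcings %||% list(),
                     names(formals(island_forcings)), "forcings",
                     unclass(island_forcings()))
  prof <- section_in(doc$profile %||% list(),
                     names(formals(tourist_profile)), "profile",
                     unclass(tourist_profile()))
  pars <- section_in(doc$params %||% list(), parameter_names(), "params",
                     unclass(island_parameters()))
  init_in <- doc$init %||% list()
  unknown <- setdiff(names(init_in), pool_names())
  if (length(unknown)) {
    abort_config(paste("unknown stock(s) under `init`:",
                       paste(unknown, collapse = ", ")),
                 field = paste0("init.", unknown[1]))
  }
  init <- do.call(carbon_pools, lapply(init_in, as.numeric))
  extra <- doc$extra_sinks %||% list()
  extra_tbl <- if (length(extra)) {
    dplyr::bind_rows(lapply(extra, tibble::as_tibble))
  } else {
    NULL
  }
  island_config(
    params = structure(pars, class = "island_parameters"),
    forcings = structure(forc, class = "island_forcings"),
    profile = structure(prof, class = "tourist_profile"),
    init = init,
    horizon = if (is.null(doc$horizon)) 1 else
      quantity_in(doc$horizon, "horizon", "horizon"),
    dt = if (is.null(doc$dt)) 1 / 12 else quantity_in(doc$dt, "dt", "dt"),
    flux_scale = unlist(doc$flux_scale) %||% numeric(),
    extra_sinks = extra_tbl,
    temp_mode = doc$temp_mode %||% "clamp",
    name = doc$name %||% "custom"
  )
}

#' Export results as CSV / JSON
#'
#' `write_trajectory_csv()` writes the tidy long trajectory (time, name,
#' type, value, unit). `write_budget_csv()` writes budget rows with shares.
#' `budget_report()` builds (and optionally writes) a machine-readable JSON
#' report: rows with shares, totals, carbon credit, and the flux mapping
#' used. Outputs are deterministic: identical inputs give byte-identical
#' files.
#'
#' @param trajectory an `island_trajectory`.
#' @param budget a `carbon_budget`.
#' @param path file to write (for `budget_report()`, `NULL` to just return
#'   the report list).
#' @param headline_mode passed to [budget_shares()].
#' @return the written path (or the report list), invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(tidy(trajectory), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_budget_csv <- function(budget, path, headline_mode = FALSE) {
  readr::write_csv(tibble::as_tibble(budget_shares(budget, headline_mode)),
                   path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
budget_report <- function(budget, path = NULL, headline_mode = FALSE) {
  shared <- budget_shares(budget, headline_mode)
  rep <- list(
    config = attr(budget, "config_name"),
    headline_mode = headline_mode,
    rows = tibble::as_tibble(shared),
    total_emission = attr(budget, "total_emission"),
    total_sink = attr(budget, "total_sink"),
    carbon_credit = attr(budget, "carbon_credit"),
    mapping = if (!is.null(attr(budget, "mapping"))) {
      tibble::as_tibble(attr(budget, "mapping"))
    }
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(path))
  }
  invisible(rep)
}
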