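# Structured configuration: JSON files with "simulation" and "scenario"
# sections; unknown keys are rejected, defaults are filled in and flagged.

.sim_keys <- function() names(formals(simulation_config))

.scen_keys <- function() setdiff(names(formals(make_bottleneck_scenario)),
                                 c("target", "obstacles", "profile"))

#' Load a simulation configuration file
#'
#' Reads a JSON file with optional `"simulation"` and `"scenario"` sections
#' (bare top-level keys are routed to whichever section knows them). Missing
#' keys take the standard-scenario defaults; unknown keys and out-of-range
#' values are rejected with an error naming the offending key. An empty file
#' (`{}`) yields the full default standard scenario.
#'
#' @param path JSON file path.
#' @return list with elements `config` (a [simulation_config()]),
#'   `scenario_args` (arguments for [make_bottleneck_scenario()]) and
#'   `defaulted` (character vector of keys filled with defaults).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0L) raw <- list()
  sim <- if (!is.null(raw$simulation)) as.list(raw$simulation) else list()
  scen <- if (!is.null(raw$scenario)) as.list(raw$scenario) else list()
  extra <- raw[setdiff(names(raw), c("simulation", "scenario"))]
  for (key in names(extra)) {
    if (key %in% .sim_keys()) sim[[key]] <- extra[[key]]
    else if (key %in% .scen_keys()) scen[[key]] <- extra[[key]]
    else stop("unknown configuration key: ", key)
  }
  bad <- setdiff(names(sim), .sim_keys())
  if (length(bad)) stop("unknown simulation key: ", bad[1])
  bad <- setdiff(names(scen), .scen_keys())
  if (length(bad)) stop("unknown scenario key: ", bad[1])
  config <- tryCatch(do.call(simulation_config, sim),
                     error = function(e)
                       stop("invalid simulation setting: ",
                            conditionMessage(e), call. = FALSE))
  defaulted <- c(setdiff(.sim_keys(), names(sim)),
                 setdiff(.scen_keys(), names(scen)))
  if (is.null(scen$n_agents)) scen$n_agents <- config$n_agents
  list(config = config, scenario_args = scen, defaulted = defaulted)
}

#' Save a simulation configuration file
#'
#' Writes the JSON counterpart of [load_config()]; `load_config(save_config(x))`
#' round-trips.
#'
#' @param config a [simulation_config()].
#' @param path output JSON path.
#' @param scenario_args optional list of [make_bottleneck_scenario()]
#'   arguments to store in the `"scenario"` section.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, scenario_args = list()) {
  stopifnot(inherits(config, "simulation_config"))
  jsonlite::write_json(list(simulation = unclass(config),
                            scenario = scenario_args),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
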