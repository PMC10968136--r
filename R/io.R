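# Trajectory and summary I/O. The interchange format is long-format CSV with
# the configuration echoed as a JSON sidecar (<path>.config.json) so that
# summaries recomputed from disk match the in-memory ones.

#' Write or read a trajectory CSV
#'
#' One row per agent per snapshot with columns `iteration, agent, role, x, y,
#' vx, vy, vgx, vgy, L, v_c, r, theta, dist, frozen`. The simulation
#' configuration is written alongside as `<path>.config.json` and re-attached
#' on read, so [summarize_trajectory()] works on a read-back trajectory.
#'
#' @param traj a [run_simulation()] trajectory.
#' @param path CSV file path.
#' @return `read_trajectory` returns the trajectory data.frame;
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- attr(traj, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".config.json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(traj, "config") <- do.call(simulation_config, as.list(cfg))
  }
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write summary tables to CSV
#'
#' @param summary a [summarize_trajectory()] result.
#' @param prefix file path prefix; writes `<prefix>_group_distance.csv`,
#'   `<prefix>_agent_series.csv` and `<prefix>_agent_summary.csv`.
#' @return `prefix`, invisibly.
#' @export
write_summary <- function(summary, prefix) {
  stopifnot(inherits(summary, "crowd_summary"))
  utils::write.csv(summary$group_distance,
                   paste0(prefix, "_group_distance.csv"), row.names = FALSE)
  utils::write.csv(summary$agent_series,
                   paste0(prefix, "_agent_series.csv"), row.names = FALSE)
  utils::write.csv(summary$agent_summary,
                   paste0(prefix, "_agent_summary.csv"), row.names = FALSE)
  invisible(prefix)
}
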