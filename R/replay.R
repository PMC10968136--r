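# Replayable location-stream adapter: runs the advisory and social-distance
# compliance computations against externally supplied positions (e.g. from
# wireless trackers) instead of simulated ones.

#' Location stream
#'
#' A time-ordered table of `(timestamp, agent_id, x, y)` records standing in
#' for the tracker network's position feed.
#'
#' @param records data.frame with columns `timestamp`, `agent_id`, `x`, `y`.
#' @param source `"simulated"` or `"replay"` provenance tag.
#' @return data.frame of class `location_stream`.
#' @export
location_stream <- function(records, source = c("replay", "simulated")) {
  source <- match.arg(source)
  need <- c("timestamp", "agent_id", "x", "y")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(records$timestamp))
    records <- records[order(records$timestamp, records$agent_id), ]
  if (!all(is.finite(records$x)) || !all(is.finite(records$y)))
    stop("positions must be finite")
  structure(records, class = c("location_stream", "data.frame"),
            source = source)
}

#' Convert a simulated trajectory into a location stream
#'
#' @param traj a [run_simulation()] trajectory.
#' @param dt time step (s); defaults to the trajectory config's.
#' @return a [location_stream()] with `source = "simulated"`.
#' @export
trajectory_to_stream <- function(traj, dt = NULL) {
  if (is.null(dt)) {
    cfg <- attr(traj, "config")
    dt <- if (is.null(cfg)) 1 else cfg$dt
  }
  location_stream(data.frame(timestamp = traj$iteration * dt,
                             agent_id = traj$agent,
                             x = traj$x, y = traj$y),
                  source = "simulated")
}

#' Replay a location stream through the advisory layer
#'
#' For each agent at each timestamp after the first, computes the heading
#' advisory (angle between the displacement since the previous fix and the
#' direction to the target), the finite-difference speed, the agent's
#' required social distance, the distance to its nearest neighbor at that
#' timestamp, and a compliance flag (`TRUE` when no other agent is closer
#' than the required distance). Agents missing at a timestamp produce a gap
#' warning and are skipped at that step.
#'
#' @param stream a [location_stream()].
#' @param sc the [scenario()] defining target, roles and profile; stream
#'   agent ids must match scenario agents.
#' @param config a [simulation_config()] (for the neighborhood radius).
#' @return data.frame with columns `timestamp`, `agent_id`, `theta`, `speed`,
#'   `r_required`, `nearest_dist`, `compliant`.
#' @export
replay_stream <- function(stream, sc, config = simulation_config()) {
  stopifnot(inherits(sc, "scenario"))
  n <- nrow(sc$positions)
  ids <- sort(unique(stream$agent_id))
  if (!all(ids %in% seq_len(n)))
    stop("stream agent ids do not match the scenario")
  disabled <- sc$roles == "disabled"
  times <- sort(unique(stream$timestamp))
  out <- vector("list", length(times))
  prev <- NULL
  prev_t <- NA_real_
  for (ti in seq_along(times)) {
    t_now <- times[ti]
    rows <- stream[stream$timestamp == t_now, ]
    present <- rows$agent_id
    missing <- setdiff(seq_len(n), present)
    if (length(missing))
      warning(sprintf("gap at t=%g: agent(s) %s missing; advisory skipped",
                      t_now, paste(missing, collapse = ",")))
    P <- matrix(NA_real_, n, 2)
    P[rows$agent_id, ] <- cbind(rows$x, rows$y)
    if (ti > 1L) {
      dtt <- t_now - prev_t
      D <- as.matrix(stats::dist(P))
      diag(D) <- NA
      res <- lapply(intersect(present, which(!is.na(prev[, 1]))), function(k) {
        disp <- P[k, ] - prev[k, ]
        v <- disp / dtt
        theta <- heading_advisory(prev[k, ], P[k, ], sc$target)
        r_req <- if (all(abs(sc$target - P[k, ]) < 1e-12)) NA_real_
        else social_distance(v, P[k, ], sc$target, sc$profile, disabled[k])
        nd <- suppressWarnings(min(D[k, ], na.rm = TRUE))
        if (!is.finite(nd)) nd <- NA_real_
        data.frame(timestamp = t_now, agent_id = k, theta = theta,
                   speed = sqrt(sum(v^2)), r_required = r_req,
                   nearest_dist = nd,
                   compliant = is.na(r_req) | is.na(nd) | nd >= r_req)
      })
      out[[ti]] <- if (length(res)) do.call(rbind, res) else NULL
    }
    prev <- P
    prev_t <- t_now
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
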