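# The simulation loop: per-iteration adaptation (geometry query, speed and
# distance laws, velocity composition) and combination (velocity diffusion)
# for all agents, with noise injection, trajectory recording and summaries.

#' Simulation configuration
#'
#' Bundles the model's tunable parameters. Defaults follow the standard
#' study conditions: 40 agents, one with disabilities, diffusion step sizes
#' `mu = mu_v = 0.05`, velocity-composition weights
#' `{lambda, beta, gamma} = {0.5, 1, 1}`, obstacle safety coefficient
#' `alpha = 0.5`, unit time step, 200 iterations.
#'
#' @param n_agents number of agents.
#' @param disabled_ids integer ids of agents with disabilities (used when a
#'   scenario is generated from this config).
#' @param mu,mu_v diffusion step sizes, in (0, 1).
#' @param lambda,beta,gamma velocity-composition weights (`lambda` in
#'   \[0, 1\]; `beta`, `gamma` non-negative).
#' @param alpha obstacle safety margin coefficient (m), non-negative.
#' @param dt time step (s), positive.
#' @param R neighborhood (communication) radius (m), positive.
#' @param n_iterations number of simulation steps.
#' @param seed integer RNG seed; recorded in every output.
#' @param sigma_speed std. dev. of the zero-mean Gaussian noise added to each
#'   velocity component (m/s).
#' @param sigma_pos std. dev. of the positional jitter added after each step
#'   (m), emulating ranging error in the location estimates.
#' @param weight_rule combination-weight rule, `"uniform"` or `"metropolis"`.
#' @param wall_margin minimum wall clearance (m).
#' @param arrival_tol agents within this distance of the target freeze (m).
#' @param tau_diffusion logical; when `TRUE` the shared target is also
#'   estimated by ATC diffusion instead of being known exactly (off in the
#'   standard scenario, where the target is fixed and known).
#' @param centerline_resolution sampling step of the cached centerline used
#'   for per-agent chord queries (m).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_agents = 40, disabled_ids = 5L,
                              mu = 0.05, mu_v = 0.05,
                              lambda = 0.5, beta = 1, gamma = 1,
                              alpha = 0.5, dt = 1, R = 5,
                              n_iterations = 200, seed = 1,
                              sigma_speed = 0.05, sigma_pos = 0.02,
                              weight_rule = c("uniform", "metropolis"),
                              wall_margin = 0.3, arrival_tol = 0.5,
                              tau_diffusion = FALSE,
                              centerline_resolution = 0.02) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(mu > 0, mu < 1, mu_v > 0, mu_v < 1,
            lambda >= 0, lambda <= 1, beta >= 0, gamma >= 0, alpha >= 0,
            dt > 0, R > 0, n_iterations >= 0,
            sigma_speed >= 0, sigma_pos >= 0,
            wall_margin >= 0, arrival_tol >= 0)
  structure(list(n_agents = n_agents, disabled_ids = as.integer(disabled_ids),
                 mu = mu, mu_v = mu_v, lambda = lambda, beta = beta,
                 gamma = gamma, alpha = alpha, dt = dt, R = R,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 sigma_speed = sigma_speed, sigma_pos = sigma_pos,
                 weight_rule = weight_rule, wall_margin = wall_margin,
                 arrival_tol = arrival_tol, tau_diffusion = tau_diffusion,
                 centerline_resolution = centerline_resolution),
            class = "simulation_config")
}

#' Euclidean distance to the target
#'
#' @param w position(s): length-2 numeric or `n x 2` matrix.
#' @param target numeric length-2 target.
#' @return numeric vector of distances (m).
#' @export
distance_to_target <- function(w, target) {
  W <- if (is.matrix(w)) w else matrix(w, ncol = 2)
  sqrt((W[, 1] - target[1])^2 + (W[, 2] - target[2])^2)
}

#' Gaussian velocity noise
#'
#' Adds independent zero-mean Gaussian perturbations to each velocity
#' component, emulating natural speed variability. Uses the current RNG
#' stream; `sigma = 0` returns the input unchanged.
#'
#' @param v numeric vector or matrix of velocity components (m/s).
#' @param sigma standard deviation (m/s), non-negative.
#' @return perturbed velocities, same shape as `v`.
#' @export
inject_noise <- function(v, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(v)
  v + stats::rnorm(length(v), 0, sigma)
}

#' Run the cooperative crowd simulation
#'
#' Executes the full adapt-then-combine loop. Per iteration and per agent:
#' neighborhood update, chord (corridor-width) query, width-regulated speed
#' factor, goal-seeking or obstacle-avoidance velocity, speed-dependent
#' social distance, cohesion term, velocity composition, noise injection,
#' role-specific speed capping, position update with wall-clearance
#' projection, heading advisory, and finally the network-wide velocity
#' diffusion combination. Updates are synchronous: every agent uses the
#' previous iteration's neighbor states. Agents within `arrival_tol` of the
#' target freeze but remain visible to neighbors for distance keeping.
#'
#' @param sc a [scenario()].
#' @param config a [simulation_config()].
#' @return A long-format data.frame of class `trajectory` with one row per
#'   agent per snapshot and columns `iteration` (0 = initial state), `agent`,
#'   `role`, `x`, `y`, `vx`, `vy`, `vgx`, `vgy`, `L` (chord length), `v_c`
#'   (speed factor), `r` (social distance), `theta` (heading advisory, rad),
#'   `dist` (distance to target) and `frozen`. The scenario and config ride
#'   along as attributes.
#' @export
run_simulation <- function(sc, config = simulation_config()) {
  stopifnot(inherits(sc, "scenario"), inherits(config, "simulation_config"))
  n <- nrow(sc$positions)
  if (!is.null(config$n_agents) && config$n_agents != n)
    stop(sprintf("config expects %d agents but scenario has %d",
                 config$n_agents, n))
  profile <- sc$profile
  disabled <- sc$roles == "disabled"
  vmax_role <- ifelse(disabled,
                      profile$v_max * profile$disabled_speed_factor,
                      profile$v_max)
  cl <- .centerline_cached(sc$walls, config$centerline_resolution)

  set.seed(config$seed)
  W <- sc$positions
  V <- matrix(0, n, 2)
  Vg <- matrix(0, n, 2)
  tau <- matrix(rep(sc$target, each = n), n, 2)
  frozen <- distance_to_target(W, sc$target) <= config$arrival_tol

  snap <- function(iter, W, V, Vg, L, v_c, r, theta, frozen) {
    data.frame(iteration = iter, agent = seq_len(n), role = sc$roles,
               x = W[, 1], y = W[, 2], vx = V[, 1], vy = V[, 2],
               vgx = Vg[, 1], vgy = Vg[, 2],
               L = L, v_c = v_c, r = r, theta = theta,
               dist = distance_to_target(W, sc$target), frozen = frozen)
  }

  chord_len <- function(p) {
    d <- .chord_seg_dist(cl, p)
    cand <- which(d <= min(d) + attr(cl, "resolution"))
    j <- cand[which.min(cl$chord[cand])]
    cl$chord[j]
  }

  # Initial snapshot: derived quantities at rest.
  L0 <- vapply(seq_len(n), function(k) chord_len(W[k, ]), numeric(1))
  vc0 <- speed_factor(L0, profile, disabled)
  r0 <- vapply(seq_len(n), function(k)
    social_distance(c(0, 0), W[k, ], sc$target, profile, disabled[k]),
    numeric(1))
  out <- vector("list", config$n_iterations + 1L)
  out[[1L]] <- snap(0L, W, V, Vg, L0, vc0, r0, NA_real_, frozen)

  for (i in seq_len(config$n_iterations)) {
    nbhd <- find_neighborhoods(W, config$R)
    A <- build_weights(nbhd, config$weight_rule)
    if (config$tau_diffusion) {
      tau <- atc_target_step(tau, matrix(rep(sc$target, each = n), n, 2),
                             config$mu, A)$tau
    }
    L <- rep(NA_real_, n)
    v_c <- rep(NA_real_, n)
    r <- rep(NA_real_, n)
    Vnew <- matrix(0, n, 2)
    for (k in seq_len(n)) {
      if (frozen[k]) next
      tgt <- if (config$tau_diffusion) tau[k, ] else sc$target
      L[k] <- chord_len(W[k, ])
      v_c[k] <- speed_factor(L[k], profile, disabled[k])
      obs_active <- NULL
      if (length(sc$obstacles)) {
        deff <- vapply(sc$obstacles, function(o)
          max(sqrt(sum((W[k, ] - o$position)^2)) - o$margin, 1e-6),
          numeric(1))
        jmin <- which.min(deff)
        if (deff[jmin] < config$R) {
          o <- sc$obstacles[[jmin]]
          obs_active <- obstacle(o$position, config$alpha)
        }
      }
      v_a <- goal_or_avoid_velocity(W[k, ], tgt, v_c[k], obs_active, config$R)
      r[k] <- social_distance(V[k, ], W[k, ], tgt, profile, disabled[k])
      others <- setdiff(nbhd[[k]], k)
      delta <- if (length(others)) {
        cohesion_term(W[k, ], W[others, , drop = FALSE], r[k])
      } else c(0, 0)
      v <- compose_velocity(v_a, Vg[k, ], delta,
                            config$lambda, config$beta, config$gamma)
      v <- inject_noise(v, config$sigma_speed)
      sp <- sqrt(sum(v^2))
      if (sp > vmax_role[k]) v <- v * vmax_role[k] / sp
      Vnew[k, ] <- v
    }
    Wnew <- W + config$dt * Vnew
    if (config$sigma_pos > 0) {
      jitter <- matrix(stats::rnorm(2L * n, 0, config$sigma_pos), n, 2)
      Wnew[!frozen, ] <- Wnew[!frozen, , drop = FALSE] +
        jitter[!frozen, , drop = FALSE]
    }
    Wnew <- .project_clearance(sc$walls, Wnew, sc$wall_margin,
                               config$centerline_resolution)
    Wnew[frozen, ] <- W[frozen, , drop = FALSE]
    theta <- vapply(seq_len(n), function(k)
      heading_advisory(W[k, ], Wnew[k, ], sc$target), numeric(1))
    Vg <- atc_velocity_step(Vg, Vnew, config$mu_v, A)$vg
    W <- Wnew
    V <- Vnew
    frozen <- frozen | distance_to_target(W, sc$target) <= config$arrival_tol
    out[[i + 1L]] <- snap(i, W, V, Vg, L, v_c, r, theta, frozen)
  }

  traj <- do.call(rbind, out)
  attr(traj, "scenario") <- sc
  attr(traj, "config") <- config
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Summaries of a simulated trajectory
#'
#' Produces (a) the mean distance to target per role per iteration, (b) the
#' per-agent time series of chord length and speed factor, and (c) per-agent
#' mean neighbor distance and mean speed over the run.
#'
#' @param traj a [run_simulation()] trajectory (or one read back from CSV
#'   with its config sidecar).
#' @param R neighborhood radius (m) used for the neighbor-distance summary;
#'   defaults to the radius recorded in the trajectory's config.
#' @return list of class `crowd_summary` with data.frames `group_distance`,
#'   `agent_series` and `agent_summary`.
#' @export
summarize_trajectory <- function(traj, R = NULL) {
  stopifnot(nrow(traj) > 0)
  if (is.null(R)) {
    cfg <- attr(traj, "config")
    if (is.null(cfg)) stop("supply R: trajectory carries no config")
    R <- cfg$R
  }
  gd <- stats::aggregate(dist ~ iteration + role, data = traj, FUN = mean)
  names(gd)[names(gd) == "dist"] <- "mean_dist"
  gd <- gd[order(gd$iteration, gd$role), ]
  rownames(gd) <- NULL

  series <- traj[, c("iteration", "agent", "role", "L", "v_c")]

  iters <- split(traj, traj$iteration)
  per_agent_nb <- lapply(iters, function(d) {
    d <- d[order(d$agent), ]
    P <- cbind(d$x, d$y)
    D <- as.matrix(stats::dist(P))
    diag(D) <- NA
    D[D > R] <- NA
    rowMeans(D, na.rm = TRUE)
  })
  nbmat <- do.call(rbind, per_agent_nb) # iterations x agents
  speedmat <- do.call(rbind, lapply(iters, function(d) {
    d <- d[order(d$agent), ]
    sqrt(d$vx^2 + d$vy^2)
  }))
  agents <- sort(unique(traj$agent))
  roles <- traj$role[match(agents, traj$agent)]
  agg <- data.frame(agent = agents, role = roles,
                    mean_neighbor_distance = colMeans(nbmat, na.rm = TRUE),
                    mean_speed = colMeans(speedmat))
  rownames(agg) <- NULL
  structure(list(group_distance = gd, agent_series = series,
                 agent_summary = agg),
            class = "crowd_summary")
}

#' @export
print.crowd_summary <- function(x, ...) {
  last <- max(x$group_distance$iteration)
  cat("<crowd_summary>\n final mean distance to target by role:\n")
  print(x$group_distance[x$group_distance$iteration == last, ],
        row.names = FALSE)
  cat(" per-agent summary (head):\n")
  print(utils::head(x$agent_summary), row.names = FALSE)
  invisible(x)
}

#' Validate a trajectory against the model invariants
#'
#' Checks wall containment (clearance at least the margin), role-specific
#' speed caps, role-specific social-distance ranges, strictly increasing
#' iteration index and the expected snapshot count.
#'
#' @param traj a trajectory data.frame.
#' @param sc the [scenario()] it was produced from (defaults to the attached
#'   attribute).
#' @param config the [simulation_config()] used (defaults to the attached
#'   attribute).
#' @return list with `ok` (logical) and `violations` (data.frame with columns
#'   `iteration`, `agent`, `check`, `value`).
#' @export
validate_trajectory <- function(traj, sc = attr(traj, "scenario"),
                                config = attr(traj, "config")) {
  if (is.null(sc) || is.null(config))
    stop("scenario and config are required (attach or supply them)")
  v <- list()
  addv <- function(it, ag, check, value)
    data.frame(iteration = it, agent = ag, check = check, value = value)

  clear <- wall_clearance(sc$walls, cbind(traj$x, traj$y))
  bad <- which(clear < sc$wall_margin - 1e-9)
  if (length(bad))
    v[[length(v) + 1L]] <- addv(traj$iteration[bad], traj$agent[bad],
                                "wall_clearance", clear[bad])

  profile <- sc$profile
  vmax_role <- ifelse(traj$role == "disabled",
                      profile$v_max * profile$disabled_speed_factor,
                      profile$v_max)
  sp <- sqrt(traj$vx^2 + traj$vy^2)
  bad <- which(sp > vmax_role + 1e-9)
  if (length(bad))
    v[[length(v) + 1L]] <- addv(traj$iteration[bad], traj$agent[bad],
                                "speed_cap", sp[bad])

  rlo <- ifelse(traj$role == "disabled",
                profile$r_min * profile$disabled_distance_factor,
                profile$r_min)
  rhi <- ifelse(traj$role == "disabled",
                profile$r_max * profile$disabled_distance_factor,
                profile$r_max)
  bad <- which(!is.na(traj$r) & (traj$r < rlo - 1e-9 | traj$r > rhi + 1e-9))
  if (length(bad))
    v[[length(v) + 1L]] <- addv(traj$iteration[bad], traj$agent[bad],
                                "social_distance_range", traj$r[bad])

  iters <- sort(unique(traj$iteration))
  if (!all(diff(iters) > 0) ||
      length(iters) != config$n_iterations + 1L)
    v[[length(v) + 1L]] <- addv(NA, NA, "snapshot_count", length(iters))

  violations <- if (length(v)) do.call(rbind, v)
  else data.frame(iteration = integer(), agent = integer(),
                  check = character(), value = numeric())
  list(ok = nrow(violations) == 0L, violations = violations)
}
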