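# Scenario construction: bottleneck corridors with a shared target and
# randomly seeded agents, plus CSV/JSON scenario I/O.

#' Construct a scenario
#'
#' Low-level constructor validating the scenario invariants; most users will
#' call [make_bottleneck_scenario()] instead.
#'
#' @param walls a [wall_pair()].
#' @param target numeric length-2 shared target, inside the corridor.
#' @param positions `n x 2` matrix of initial agent positions.
#' @param roles character vector, `"general"` or `"disabled"`, one per agent.
#' @param obstacles list of [obstacle()] objects.
#' @param profile a [speed_profile()].
#' @param wall_margin minimum wall clearance (m) agents must keep.
#' @param params optional list of generator parameters (kept for provenance).
#' @return list of class `scenario`.
#' @export
scenario <- function(walls, target, positions, roles,
                     obstacles = list(), profile = speed_profile(),
                     wall_margin = 0.3, params = list()) {
  stopifnot(inherits(walls, "wall_pair"))
  positions <- as.matrix(positions)
  target <- as.numeric(target)
  if (nrow(positions) != length(roles))
    stop("one role per agent is required")
  if (!all(roles %in% c("general", "disabled")))
    stop("roles must be 'general' or 'disabled'")
  if (wall_clearance(walls, target)[1] <= 0)
    stop("target must lie inside the corridor")
  cl <- wall_clearance(walls, positions)
  if (any(cl < wall_margin - 1e-9))
    stop("initial positions must keep the wall-clearance margin")
  structure(list(walls = walls, target = target, positions = positions,
                 roles = roles, obstacles = obstacles, profile = profile,
                 wall_margin = wall_margin, params = params),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d agents (%d disabled), target (%.2f, %.2f)\n",
              nrow(x$positions), sum(x$roles == "disabled"),
              x$target[1], x$target[2]))
  print(x$walls)
  invisible(x)
}

# Cosine-tapered half-width: flat entry, smooth taper down to the throat,
# flat throat, taper back up, flat exit.
.bottleneck_halfwidth <- function(x, end_width, throat_width,
                                  throat_center, throat_length, taper_length) {
  e <- end_width / 2
  th <- throat_width / 2
  xa <- throat_center - throat_length / 2 - taper_length
  xb <- throat_center - throat_length / 2
  xc <- throat_center + throat_length / 2
  xd <- throat_center + throat_length / 2 + taper_length
  h <- rep(e, length(x))
  i <- x >= xa & x < xb
  h[i] <- th + (e - th) * (1 + cos(pi * (x[i] - xa) / (xb - xa))) / 2
  h[x >= xb & x <= xc] <- th
  i <- x > xc & x <= xd
  h[i] <- th + (e - th) * (1 - cos(pi * (x[i] - xc) / (xd - xc))) / 2
  h
}

#' Bottleneck corridor scenario
#'
#' Builds the standard study setting: a straight corridor whose width tapers
#' smoothly (cosine blend) from `end_width` at both ends down to
#' `throat_width` at a narrow throat, a shared target near the right end, and
#' `n_agents` agents (of which `n_disabled` have disabilities) placed
#' uniformly at random in the left entry region with pairwise spacing at
#' least `r_min` and wall clearance at least `wall_margin`. Generation is
#' deterministic for a given `seed`. With `throat_width == end_width` the
#' corridor degenerates to parallel walls.
#'
#' By convention (mirroring the reference layout in which agent 5 is the
#' wheelchair user) the first disabled role is assigned to agent 5 when the
#' crowd is large enough.
#'
#' @param n_agents number of agents.
#' @param n_disabled number of agents with disabilities (`< n_agents`).
#' @param corridor_length,end_width,throat_width corridor dimensions (m).
#' @param throat_center,throat_length,taper_length throat placement (m).
#' @param entry_length length of the left entry region agents start in (m).
#' @param target target point; default 2 m short of the right end on the
#'   centerline.
#' @param obstacles list of [obstacle()] objects.
#' @param profile a [speed_profile()].
#' @param wall_margin minimum wall clearance (m).
#' @param seed integer RNG seed for the initial positions.
#' @param dx wall sampling step (m).
#' @param max_attempts rejection-sampling cap before declaring the packing
#'   infeasible.
#' @return a [scenario()].
#' @examples
#' sc <- make_bottleneck_scenario(n_agents = 5, seed = 1)
#' sc
#' @export
make_bottleneck_scenario <- function(n_agents = 40, n_disabled = 1,
                                     corridor_length = 60, end_width = 10,
                                     throat_width = 2, throat_center = 35,
                                     throat_length = 4, taper_length = 5,
                                     entry_length = 8, target = NULL,
                                     obstacles = list(),
                                     profile = speed_profile(),
                                     wall_margin = 0.3, seed = 1,
                                     dx = 0.05, max_attempts = 20000) {
  stopifnot(n_disabled < n_agents, n_agents >= 1,
            throat_width >= profile$L_min, throat_width <= end_width)
  hw <- function(x) .bottleneck_halfwidth(x, end_width, throat_width,
                                          throat_center, throat_length,
                                          taper_length)
  walls <- wall_pair(function(x) hw(x), function(x) -hw(x),
                     c(0, corridor_length), dx = dx)
  if (is.null(target)) target <- c(corridor_length - 2, 0)

  set.seed(seed)
  ymax <- end_width / 2 - wall_margin - 0.05
  pos <- matrix(NA_real_, n_agents, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n_agents) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("infeasible packing: %d agents do not fit in the entry region", n_agents))
    cand <- c(stats::runif(1, 1, 1 + entry_length), stats::runif(1, -ymax, ymax))
    if (placed > 0L) {
      d <- sqrt((pos[seq_len(placed), 1] - cand[1])^2 +
                  (pos[seq_len(placed), 2] - cand[2])^2)
      if (min(d) < profile$r_min) next
    }
    if (wall_clearance(walls, cand)[1] < wall_margin) next
    placed <- placed + 1L
    pos[placed, ] <- cand
  }

  roles <- rep("general", n_agents)
  ids <- if (n_agents >= 5) utils::head(c(5L, setdiff(seq_len(n_agents), 5L)),
                                        n_disabled)
  else utils::head(seq_len(n_agents), n_disabled)
  roles[ids] <- "disabled"

  scenario(walls, target, pos, roles, obstacles = obstacles,
           profile = profile, wall_margin = wall_margin,
           params = list(n_agents = n_agents, n_disabled = n_disabled,
                         corridor_length = corridor_length,
                         end_width = end_width, throat_width = throat_width,
                         throat_center = throat_center,
                         throat_length = throat_length,
                         taper_length = taper_length,
                         entry_length = entry_length, seed = seed, dx = dx))
}

#' Write or read a scenario
#'
#' The wall geometry goes to `<prefix>_walls.csv` (columns `x, y_upper,
#' y_lower`) and everything else (target, positions, roles, obstacles,
#' profile, margins, generator parameters) to a JSON sidecar
#' `<prefix>_scenario.json`.
#'
#' @param sc a [scenario()].
#' @param prefix file path prefix.
#' @return `read_scenario` returns a [scenario()]; `write_scenario` returns
#'   `prefix` invisibly.
#' @export
write_scenario <- function(sc, prefix) {
  write_walls(sc$walls, paste0(prefix, "_walls.csv"))
  side <- list(
    target = sc$target,
    positions = unname(apply(sc$positions, 1, function(r) r, simplify = FALSE)),
    roles = sc$roles,
    obstacles = lapply(sc$obstacles, function(o)
      list(position = o$position, margin = o$margin)),
    profile = unclass(sc$profile),
    wall_margin = sc$wall_margin,
    dx = sc$walls$dx,
    params = sc$params)
  jsonlite::write_json(side, paste0(prefix, "_scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, "_scenario.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  walls <- read_walls(paste0(prefix, "_walls.csv"),
                      dx = if (!is.null(side$dx)) side$dx else 0.05)
  pos <- if (is.matrix(side$positions)) side$positions
  else do.call(rbind, lapply(side$positions, as.numeric))
  obstacles <- lapply(side$obstacles, function(o)
    obstacle(as.numeric(o$position), o$margin))
  profile <- do.call(speed_profile, as.list(side$profile))
  scenario(walls, as.numeric(side$target), pos, side$roles,
           obstacles = obstacles, profile = profile,
           wall_margin = side$wall_margin,
           params = if (is.null(side$params)) list() else as.list(side$params))
}
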