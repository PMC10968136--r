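# Per-agent speed/distance laws and velocity composition: chord -> speed,
# speed -> social distance (with disabled-agent scaling), cohesion,
# goal-seeking / obstacle avoidance, position update, heading advisory.

#' Speed and social-distance profile
#'
#' Operational bounds shared by all agents: walking speeds between one slow
#' step and three fast strides per second (`v_min` = 0.6, `v_max` = 3.6 m/s,
#' mean 2.1 m/s), social distance between `r_min` = 1 and `r_max` = 2 m, and
#' corridor widths of practical interest between `L_min` = 1 and
#' `L_max` = 10 m. Agents with disabilities walk at half the general-public
#' speed and keep twice the social distance.
#'
#' @param v_min,v_max walking-speed bounds (m/s).
#' @param r_min,r_max social-distance bounds (m).
#' @param L_min,L_max chord-length (corridor-width) bounds (m).
#' @param disabled_speed_factor multiplier on speed for agents with
#'   disabilities.
#' @param disabled_distance_factor multiplier on social distance for agents
#'   with disabilities.
#' @return list of class `speed_profile`.
#' @export
speed_profile <- function(v_min = 0.6, v_max = 3.6,
                          r_min = 1, r_max = 2,
                          L_min = 1, L_max = 10,
                          disabled_speed_factor = 0.5,
                          disabled_distance_factor = 2) {
  stopifnot(v_min < v_max, r_min < r_max, L_min < L_max,
            disabled_speed_factor > 0, disabled_distance_factor > 0)
  structure(list(v_min = v_min, v_max = v_max, r_min = r_min, r_max = r_max,
                 L_min = L_min, L_max = L_max,
                 disabled_speed_factor = disabled_speed_factor,
                 disabled_distance_factor = disabled_distance_factor),
            class = "speed_profile")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0))
  v / n
}

#' Chord-to-speed mapping
#'
#' The speed factor decreases affinely with the local corridor width (chord
#' length): narrow passages are crossed quickly, wide ones slowly. Chords
#' outside `[L_min, L_max]` are clamped first, so the general-public range is
#' exactly `[v_min, v_max]`. Agents with disabilities get the same mapping
#' scaled by `disabled_speed_factor` (half speed by default).
#'
#' @param L chord length(s) (m), positive; vectorized.
#' @param profile a [speed_profile()].
#' @param disabled logical flag (scalar or vectorized over `L`).
#' @return speed(s) in m/s.
#' @examples
#' speed_factor(5.47) # 2.11 m/s for the general public
#' speed_factor(4.57, disabled = TRUE) # 1.2 m/s on a wheelchair
#' @export
speed_factor <- function(L, profile = speed_profile(), disabled = FALSE) {
  stopifnot(all(L > 0))
  Lc <- pmin(pmax(L, profile$L_min), profile$L_max)
  v <- (profile$L_max - Lc) / (profile$L_max - profile$L_min) *
    (profile$v_max - profile$v_min) + profile$v_min
  v * ifelse(disabled, profile$disabled_speed_factor, 1)
}

#' Speed-dependent social distance
#'
#' The desired inter-agent spacing decreases affinely with the agent's speed
#' toward the target (the scalar projection of its velocity onto the unit
#' target direction): fast agents in narrow passages accept the minimum
#' spacing, slow agents in wide areas keep the maximum. The base value is
#' clamped to `[r_min, r_max]` and then doubled (by
#' `disabled_distance_factor`) for agents with disabilities.
#'
#' @param v numeric length-2 velocity vector (m/s).
#' @param w numeric length-2 agent position (m).
#' @param target numeric length-2 target position (m); must differ from `w`.
#' @param profile a [speed_profile()].
#' @param disabled logical flag.
#' @return social distance (m).
#' @export
social_distance <- function(v, w, target, profile = speed_profile(),
                            disabled = FALSE) {
  if (all(abs(target - w) < 1e-12))
    stop("agent is at the target: direction undefined (handle arrival separately)")
  proj <- sum(v * .unit(target - w))
  r <- (profile$v_max - proj) / (profile$v_max - profile$v_min) *
    (profile$r_max - profile$r_min) + profile$r_min
  r <- min(max(r, profile$r_min), profile$r_max)
  if (disabled) r <- r * profile$disabled_distance_factor
  r
}

#' Cohesion term
#'
#' Averaged attraction/repulsion keeping neighbors near the desired spacing
#' `r`: each neighbor beyond `r` pulls the agent toward it, each neighbor
#' closer than `r` pushes it away, in proportion to the spacing error.
#'
#' @param w_k numeric length-2 agent position.
#' @param neighbor_positions matrix of neighbor positions (excluding the
#'   agent itself), one row per neighbor.
#' @param r desired spacing (m).
#' @return numeric length-2 cohesion vector (m).
#' @export
cohesion_term <- function(w_k, neighbor_positions, r) {
  P <- if (is.matrix(neighbor_positions)) neighbor_positions
  else matrix(neighbor_positions, ncol = 2)
  if (nrow(P) < 1L) stop("cohesion requires at least one neighbor")
  dx <- P[, 1] - w_k[1]
  dy <- P[, 2] - w_k[2]
  dist <- sqrt(dx^2 + dy^2)
  ok <- dist > 1e-12
  if (any(!ok))
    warning("skipping coincident neighbor(s): direction undefined")
  coef <- numeric(length(dist))
  coef[ok] <- (dist[ok] - r) / dist[ok]
  c(sum(coef * dx), sum(coef * dy)) / nrow(P)
}

#' Point obstacle
#'
#' @param position numeric length-2 obstacle location (m).
#' @param margin safety margin subtracted from the distance to the obstacle
#'   (m), non-negative.
#' @return list of class `obstacle`.
#' @export
obstacle <- function(position, margin = 0.5) {
  stopifnot(length(position) == 2L, margin >= 0)
  structure(list(position = as.numeric(position), margin = margin),
            class = "obstacle")
}

#' Goal-seeking or obstacle-avoidance velocity
#'
#' Without an active obstacle the agent heads straight for the target at its
#' width-regulated speed `C`. When an obstacle's effective distance
#' `d_eff = max(||w - p|| - margin, eps)` falls below the neighborhood radius
#' `R`, the agent instead moves directly away from the obstacle with
#' magnitude `C (R / d_eff - 1)`, which switches on continuously at
#' `d_eff = R` and grows without bound as the agent closes on the obstacle.
#'
#' @param w numeric length-2 agent position.
#' @param target numeric length-2 target position.
#' @param C speed coefficient (m/s), positive — the agent's current
#'   width-regulated speed factor.
#' @param obs an [obstacle()] or `NULL`.
#' @param R neighborhood radius (m), used as the avoidance activation range.
#' @return numeric length-2 velocity vector (m/s).
#' @export
goal_or_avoid_velocity <- function(w, target, C, obs = NULL, R = 5) {
  stopifnot(C > 0)
  if (!is.null(obs)) {
    away <- w - obs$position
    d_eff <- max(sqrt(sum(away^2)) - obs$margin, 1e-6)
    if (d_eff < R)
      return(C * (R / d_eff - 1) * .unit(away))
  }
  if (all(abs(target - w) < 1e-12)) return(c(0, 0))
  C * .unit(target - w)
}

#' Velocity composition
#'
#' Blends the goal/avoidance velocity, the diffusion estimate of the
#' network's center-of-gravity velocity, and the cohesion term:
#' `v = lambda * beta * v_a + (1 - lambda) * v_g + gamma * delta`.
#'
#' @param v_a goal/avoidance velocity (m/s).
#' @param v_g center-of-gravity velocity estimate (m/s).
#' @param delta cohesion vector (m).
#' @param lambda blend between individual drive and group consensus, in
#'   \[0, 1\].
#' @param beta,gamma non-negative gains on `v_a` and `delta`.
#' @return numeric length-2 composed velocity (m/s).
#' @export
compose_velocity <- function(v_a, v_g, delta,
                             lambda = 0.5, beta = 1, gamma = 1) {
  stopifnot(lambda >= 0, lambda <= 1, beta >= 0, gamma >= 0)
  lambda * beta * v_a + (1 - lambda) * v_g + gamma * delta
}

#' Position update with wall-clearance projection
#'
#' Advances the position by `w + dt * v`; when walls are supplied, the new
#' position is projected back so its wall clearance is at least `margin`.
#'
#' @param w numeric length-2 position (m).
#' @param v numeric length-2 velocity (m/s).
#' @param dt time step (s), positive.
#' @param walls optional [wall_pair()] used for the clearance projection.
#' @param margin minimum wall clearance (m).
#' @return numeric length-2 updated position.
#' @export
advance_position <- function(w, v, dt, walls = NULL, margin = 0.3) {
  stopifnot(dt > 0)
  w2 <- w + dt * v
  if (!is.null(walls)) w2 <- drop(.project_clearance(walls, rbind(w2), margin))
  as.numeric(w2)
}

#' Heading advisory angle
#'
#' Angle between the agent's most recent movement direction and the direction
#' from its current position to the target, in `[0, pi]` radians. Delivered
#' to agents with disabilities as a course-correction cue (0 means on
#' course). Returns `NA` when the displacement is zero or the agent is at the
#' target.
#'
#' @param w_prev,w previous and current positions (length-2 numeric).
#' @param target target position (length-2 numeric).
#' @return angle in radians, or `NA_real_`.
#' @export
heading_advisory <- function(w_prev, w, target) {
  move <- w - w_prev
  to_target <- target - w
  if (sqrt(sum(move^2)) < 1e-12 || sqrt(sum(to_target^2)) < 1e-12)
    return(NA_real_)
  cosang <- sum(.unit(move) * .unit(to_target))
  acos(min(max(cosang, -1), 1))
}
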