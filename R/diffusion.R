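# ATC diffusion machinery: neighborhoods, combination weights, and the
# adapt-then-combine updates for the shared target estimate and the
# center-of-gravity velocity estimate.

#' One-hop neighborhoods
#'
#' Each agent's neighborhood is the set of agents within communication radius
#' `R` of it, including itself; the boundary is inclusive.
#'
#' @param positions `n x 2` matrix of agent positions (m).
#' @param R communication radius (m), positive.
#' @return A list of integer index vectors of class `neighborhood`, one per
#'   agent, each containing the agent itself.
#' @export
find_neighborhoods <- function(positions, R) {
  stopifnot(is.numeric(R), R > 0)
  P <- if (is.matrix(positions)) positions else matrix(positions, ncol = 2)
  D <- as.matrix(stats::dist(P))
  nb <- lapply(seq_len(nrow(P)), function(k) which(D[k, ] <= R))
  structure(nb, class = "neighborhood", R = R)
}

#' Combination weights
#'
#' Builds the `n x n` matrix of combination weights `A[l, k]` an agent `k`
#' assigns to each neighbor `l`. Every column sums to one, weights are
#' non-negative, and weights outside the neighborhood are zero.
#'
#' `uniform` assigns `1/|N_k|` to every member of `N_k`. `metropolis` assigns
#' `1/max(|N_k|, |N_l|)` to each neighbor pair and the remainder to self,
#' yielding a symmetric (doubly stochastic) matrix for undirected
#' neighborhoods.
#'
#' @param nbhd a [find_neighborhoods()] result (list of index vectors, each
#'   including self).
#' @param rule `"uniform"` (default) or `"metropolis"`.
#' @return An `n x n` numeric matrix with `colSums == 1`.
#' @export
build_weights <- function(nbhd, rule = c("uniform", "metropolis")) {
  rule <- match.arg(rule)
  n <- length(nbhd)
  A <- matrix(0, n, n)
  deg <- lengths(nbhd)
  for (k in seq_len(n)) {
    nb <- nbhd[[k]]
    if (!k %in% nb) stop("each neighborhood must include the agent itself")
    if (rule == "uniform") {
      A[nb, k] <- 1 / length(nb)
    } else {
      others <- setdiff(nb, k)
      A[others, k] <- 1 / pmax(deg[k], deg[others])
      A[k, k] <- 1 - sum(A[others, k])
    }
  }
  A
}

#' ATC update of the shared target estimate
#'
#' Runs one adapt-then-combine step on the per-agent target estimates using
#' the geometric simplification of the least-squares adaptation: each agent
#' blends its previous estimate with its new local measurement,
#' `psi_k = (1 - mu_k) tau_prev_k + mu_k tau_new_k`, then combines its
#' neighbors' intermediates with the combination weights,
#' `tau_k = sum_l A[l, k] psi_l`.
#'
#' @param tau_prev `n x 2` matrix of previous target estimates.
#' @param tau_new `n x 2` matrix of new local target measurements.
#' @param mu step size(s) in (0, 1), scalar or length `n`.
#' @param weights combination weight matrix from [build_weights()].
#' @return list with `psi` (intermediates) and `tau` (combined estimates),
#'   both `n x 2`.
#' @export
atc_target_step <- function(tau_prev, tau_new, mu, weights) {
  stopifnot(all(mu >= 0), all(mu <= 1))
  psi <- (1 - mu) * tau_prev + mu * tau_new
  list(psi = psi, tau = crossprod(weights, psi))
}

#' General least-squares diffusion adaptation
#'
#' The unsimplified adaptation step: each agent moves its estimate along its
#' unit direction vector by the scaled innovation,
#' `psi_k = tau_k + mu_k * u_k * (d_k - u_k . tau_k)`. Exposed for
#' completeness; the simulator uses the geometric simplification in
#' [atc_target_step()].
#'
#' @param tau `n x 2` matrix of current estimates.
#' @param u `n x 2` matrix of unit direction (regression) vectors.
#' @param d length-`n` vector of measured projected distances.
#' @param mu step size(s) in (0, 1).
#' @return `n x 2` matrix of adapted intermediates.
#' @export
atc_adaptation_ls <- function(tau, u, d, mu) {
  innov <- d - rowSums(u * tau)
  tau + (mu * innov) * u
}

#' ATC update of the center-of-gravity velocity estimate
#'
#' Each agent first adapts its estimate of the network's mean (center-of-
#' gravity) velocity toward its own current velocity,
#' `phi_k = (1 - mu_v) vg_prev_k + mu_v v_k`, then combines neighbors'
#' intermediates, `vg_k = sum_l A[l, k] phi_l`.
#'
#' @param vg_prev `n x 2` matrix of previous center-of-gravity estimates.
#' @param v_current `n x 2` matrix of current agent velocities (m/s).
#' @param mu_v step size(s) in (0, 1].
#' @param weights combination weight matrix from [build_weights()].
#' @return list with `phi` (intermediates) and `vg` (combined estimates).
#' @export
atc_velocity_step <- function(vg_prev, v_current, mu_v, weights) {
  stopifnot(all(mu_v > 0), all(mu_v <= 1))
  phi <- (1 - mu_v) * vg_prev + mu_v * v_current
  list(phi = phi, vg = crossprod(weights, phi))
}
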