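# Optional ggplot2 figures: corridor + agent snapshots, and the mean
# distance-to-target curves per role.

#' Plot crowd snapshots in the corridor
#'
#' Draws the walls and agent positions at the selected iterations, one facet
#' per iteration; agents with disabilities are highlighted.
#'
#' @param traj a [run_simulation()] trajectory.
#' @param iterations iterations to show; defaults to four evenly spaced ones.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj, iterations = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory needs the ggplot2 package")
  sc <- attr(traj, "scenario")
  if (is.null(sc)) stop("trajectory carries no scenario attribute")
  if (is.null(iterations)) {
    it <- sort(unique(traj$iteration))
    iterations <- unique(round(stats::quantile(it, c(0, 1 / 3, 2 / 3, 1))))
  }
  d <- traj[traj$iteration %in% iterations, ]
  wallsdf <- data.frame(x = c(sc$walls$upper[, 1], sc$walls$lower[, 1]),
                        y = c(sc$walls$upper[, 2], sc$walls$lower[, 2]),
                        side = rep(c("upper", "lower"),
                                   each = nrow(sc$walls$upper)))
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = wallsdf,
                       ggplot2::aes(group = side), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = role), size = 1.2) +
    ggplot2::annotate("point", x = sc$target[1], y = sc$target[2],
                      shape = 8, colour = "darkgreen", size = 3) +
    ggplot2::facet_wrap(~iteration, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(general = "firebrick",
                                            disabled = "black")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = NULL)
}

#' Plot mean distance to target per role over time
#'
#' @param traj a [run_simulation()] trajectory.
#' @return a ggplot object.
#' @export
plot_group_distance <- function(traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_group_distance needs the ggplot2 package")
  gd <- summarize_trajectory(traj)$group_distance
  ggplot2::ggplot(gd, ggplot2::aes(x = iteration, y = mean_dist,
                                   colour = role)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(general = "steelblue",
                                            disabled = "firebrick")) +
    ggplot2::labs(x = "iteration", y = "mean distance to target (m)",
                  colour = NULL)
}
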