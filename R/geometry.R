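# Corridor geometry: walls as polylines, equidistant centerline, inscribed
# circles and their tangent-point chords (the local corridor width).

#' Corridor wall pair
#'
#' Constructs the two-wall corridor geometry used throughout the package.
#' Walls may be given as functions of the horizontal coordinate `x` (metres)
#' or as two-column objects of sampled `(x, y)` points; either way they are
#' resampled onto a uniform grid in `x` so nearest-segment searches can use
#' index windows. The upper wall must lie strictly above the lower wall over
#' the whole domain.
#'
#' @param upper,lower wall curves: a function of `x` returning `y`, or a
#'   two-column matrix/data.frame of `(x, y)` samples, in metres.
#' @param x_range numeric length-2 closed horizontal domain (m). Required when
#'   either wall is a function; otherwise defaults to the overlap of the
#'   sampled inputs.
#' @param dx resampling step (m) for the internal polyline representation.
#' @return An object of class `wall_pair` with elements `upper`, `lower`
#'   (uniformly sampled polylines), `x_range` and `dx`.
#' @examples
#' walls <- wall_pair(function(x) 2 + 0 * x, function(x) -2 + 0 * x, c(0, 10))
#' wall_clearance(walls, c(5, 0))
#' @export
wall_pair <- function(upper, lower, x_range = NULL, dx = 0.05) {
  if (is.null(x_range)) {
    if (is.function(upper) || is.function(lower))
      stop("x_range is required when walls are given as functions")
    up <- as.matrix(upper)[, 1:2, drop = FALSE]
    lo <- as.matrix(lower)[, 1:2, drop = FALSE]
    x_range <- c(max(min(up[, 1]), min(lo[, 1])),
                 min(max(up[, 1]), max(lo[, 1])))
  }
  x_range <- as.numeric(x_range)
  if (length(x_range) != 2L || !all(is.finite(x_range)) ||
      x_range[2] <= x_range[1])
    stop("x_range must be a finite interval [x_start, x_end]")
  if (!is.numeric(dx) || dx <= 0 || dx >= diff(x_range))
    stop("dx must be positive and smaller than the domain length")
  xs <- seq(x_range[1], x_range[2], by = dx)
  if (xs[length(xs)] < x_range[2]) xs <- c(xs, x_range[2])
  up <- .resample_wall(upper, xs)
  lo <- .resample_wall(lower, xs)
  gap <- up[, 2] - lo[, 2]
  if (any(!is.finite(gap)) || any(gap <= 0))
    stop("invalid geometry: walls touch or cross (gap <= 0 somewhere)")
  w <- list(upper = up, lower = lo, x_range = x_range, dx = dx,
            cache = new.env(parent = emptyenv()))
  class(w) <- "wall_pair"
  w
}

.resample_wall <- function(w, xs) {
  if (is.function(w)) {
    y <- w(xs)
  } else {
    m <- as.matrix(w)[, 1:2, drop = FALSE]
    y <- stats::approx(m[, 1], m[, 2], xout = xs, rule = 2)$y
  }
  cbind(x = xs, y = as.numeric(y))
}

#' @export
print.wall_pair <- function(x, ...) {
  gap <- x$upper[, 2] - x$lower[, 2]
  cat(sprintf(
    "<wall_pair> x in [%.3g, %.3g] m, gap %.3g-%.3g m, %d samples (dx = %g)\n",
    x$x_range[1], x$x_range[2], min(gap), max(gap), nrow(x$upper), x$dx))
  invisible(x)
}

# Interpolated wall height at arbitrary x (walls are graphs of x).
.wall_y <- function(wall, x) stats::approx(wall[, 1], wall[, 2], xout = x, rule = 2)$y

.max_gap <- function(walls) max(walls$upper[, 2] - walls$lower[, 2])

# Nearest point on one wall polyline for each row of P (n x 2). Uses an index
# window around each query's x: safe because the nearest point's horizontal
# offset never exceeds the distance itself, which is bounded by the corridor
# gap for the interior points we query.
.wall_nearest <- function(wall, P, dx, halfwidth) {
  P <- matrix(as.numeric(P), ncol = 2)
  m <- nrow(wall)
  n <- nrow(P)
  K <- max(2L, ceiling(halfwidth / dx))
  nseg <- 2L * K
  i0 <- round((P[, 1] - wall[1, 1]) / dx) + 1L - K
  i0 <- pmin(pmax(i0, 1L), m - 1L)
  SI <- rep(i0, each = nseg) + rep.int(seq_len(nseg) - 1L, n)
  SI <- pmin(SI, m - 1L)
  ax <- wall[SI, 1]; ay <- wall[SI, 2]
  bx <- wall[SI + 1L, 1]; by <- wall[SI + 1L, 2]
  px <- rep(P[, 1], each = nseg); py <- rep(P[, 2], each = nseg)
  sx <- bx - ax; sy <- by - ay
  tt <- ((px - ax) * sx + (py - ay) * sy) / (sx * sx + sy * sy)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- ax + tt * sx; qy <- ay + tt * sy
  d2 <- (px - qx)^2 + (py - qy)^2
  dim(d2) <- c(nseg, n)
  jb <- max.col(-t(d2), ties.method = "first")
  li <- (seq_len(n) - 1L) * nseg + jb
  list(dist = sqrt(d2[li]), x = qx[li], y = qy[li])
}

# Precomputed windowed segment geometry for a fixed set of query stations xq.
.seg_window <- function(wall, xq, dx, halfwidth) {
  m <- nrow(wall)
  n <- length(xq)
  K <- max(2L, ceiling(halfwidth / dx))
  nseg <- 2L * K
  i0 <- pmin(pmax(round((xq - wall[1, 1]) / dx) + 1L - K, 1L), m - 1L)
  SI <- rep(i0, each = nseg) + rep.int(seq_len(nseg) - 1L, n)
  SI <- pmin(SI, m - 1L)
  ax <- wall[SI, 1]; ay <- wall[SI, 2]
  sx <- wall[SI + 1L, 1] - ax; sy <- wall[SI + 1L, 2] - ay
  list(ax = ax, ay = ay, sx = sx, sy = sy,
       iL2 = 1 / (sx * sx + sy * sy), nseg = nseg, n = n)
}

# Squared minimum distance per station to the windowed segments.
.seg_mind2 <- function(sw, px, py) {
  tt <- pmin(pmax(((px - sw$ax) * sw$sx + (py - sw$ay) * sw$sy) * sw$iL2, 0), 1)
  ex <- px - (sw$ax + tt * sw$sx)
  ey <- py - (sw$ay + tt * sw$sy)
  d2 <- ex * ex + ey * ey
  dim(d2) <- c(sw$nseg, sw$n)
  jb <- max.col(-t(d2), ties.method = "first")
  d2[(seq_len(sw$n) - 1L) * sw$nseg + jb]
}

.nearest_upper <- function(walls, P)
  .wall_nearest(walls$upper, P, walls$dx, .max_gap(walls) + walls$dx)
.nearest_lower <- function(walls, P)
  .wall_nearest(walls$lower, P, walls$dx, .max_gap(walls) + walls$dx)

#' Signed clearance from the corridor walls
#'
#' Minimum Euclidean distance from a point to either wall polyline, positive
#' for points inside the corridor and negative outside it.
#'
#' @param walls a [wall_pair()].
#' @param position numeric length-2 point, or an `n x 2` matrix of points.
#' @return numeric vector of signed clearances (m).
#' @export
wall_clearance <- function(walls, position) {
  P <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  du <- .nearest_upper(walls, P)$dist
  dl <- .nearest_lower(walls, P)$dist
  xcl <- pmin(pmax(P[, 1], walls$x_range[1]), walls$x_range[2])
  yu <- .wall_y(walls$upper, xcl)
  yl <- .wall_y(walls$lower, xcl)
  inside <- P[, 1] >= walls$x_range[1] & P[, 1] <= walls$x_range[2] &
    P[, 2] > yl & P[, 2] < yu
  ifelse(inside, pmin(du, dl), -pmin(du, dl))
}

#' Equidistant corridor centerline and chord table
#'
#' Samples the locus of centers of circles inscribed between the two walls
#' (points equidistant from both polylines), together with each circle's
#' radius, its tangent points on the walls, and the tangent-point chord whose
#' length is the local corridor width.
#'
#' @param walls a [wall_pair()].
#' @param resolution horizontal sampling step of the centerline (m); must be
#'   smaller than the domain length.
#' @return A data.frame of class `centerline` with columns `x`, `y` (center),
#'   `radius`, `xu`, `yu`, `xl`, `yl` (tangent points on the upper and lower
#'   walls) and `chord` (chord length, m).
#' @export
compute_centerline <- function(walls, resolution = 0.02) {
  stopifnot(inherits(walls, "wall_pair"))
  if (!is.numeric(resolution) || resolution <= 0 ||
      resolution >= diff(walls$x_range))
    stop("resolution must be positive and smaller than the domain length")
  xs <- seq(walls$x_range[1], walls$x_range[2], by = resolution)
  yu <- .wall_y(walls$upper, xs)
  yl <- .wall_y(walls$lower, xs)
  if (any(yu - yl <= 0))
    stop("invalid geometry: walls touch or cross (gap <= 0 somewhere)")
  lo <- yl + 1e-9
  hi <- yu - 1e-9
  # Bisection on g(y) = d_upper - d_lower, decreasing in y (vectorized over
  # all stations at once). The segment windows depend only on xs, so they are
  # precomputed; a half-width of half the gap plus a buffer is enough because
  # the smaller of the two distances (which decides the sign) never exceeds
  # half the local gap.
  hwin <- .max_gap(walls) / 2 + 1 + walls$dx
  swu <- .seg_window(walls$upper, xs, walls$dx, hwin)
  swl <- .seg_window(walls$lower, xs, walls$dx, hwin)
  pxu <- rep(xs, each = swu$nseg)
  pxl <- rep(xs, each = swl$nseg)
  for (it in seq_len(35L)) {
    mid <- (lo + hi) / 2
    g <- .seg_mind2(swu, pxu, rep(mid, each = swu$nseg)) -
      .seg_mind2(swl, pxl, rep(mid, each = swl$nseg))
    pos <- g > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  yc <- (lo + hi) / 2
  nu <- .nearest_upper(walls, cbind(xs, yc))
  nl <- .nearest_lower(walls, cbind(xs, yc))
  cl <- data.frame(x = xs, y = yc, radius = (nu$dist + nl$dist) / 2,
                   xu = nu$x, yu = nu$y, xl = nl$x, yl = nl$y,
                   chord = sqrt((nu$x - nl$x)^2 + (nu$y - nl$y)^2))
  attr(cl, "resolution") <- resolution
  class(cl) <- c("centerline", "data.frame")
  cl
}

# Centerline is cached on the wall_pair (geometry is immutable once built).
.centerline_cached <- function(walls, resolution = 0.02) {
  key <- sprintf("cl_%g", resolution)
  if (is.null(walls$cache[[key]]))
    walls$cache[[key]] <- compute_centerline(walls, resolution)
  walls$cache[[key]]
}

.chord_solution <- function(center, radius, pu, pl) {
  structure(list(
    tangent_upper = c(x = pu[1], y = pu[2]),
    tangent_lower = c(x = pl[1], y = pl[2]),
    center = c(x = center[1], y = center[2]),
    radius = radius,
    chord_length = sqrt(sum((pu - pl)^2))
  ), class = "chord_solution")
}

#' @export
print.chord_solution <- function(x, ...) {
  cat(sprintf(
    "<chord_solution> center (%.3f, %.3f), radius %.3f m, chord %.3f m\n",
    x$center[1], x$center[2], x$radius, x$chord_length))
  invisible(x)
}

#' Inscribed circle at a given horizontal station
#'
#' Finds the circle tangent to both walls whose center lies on the equidistant
#' centerline at horizontal coordinate `center_x`, and the chord joining its
#' two tangent points.
#'
#' @param walls a [wall_pair()].
#' @param center_x horizontal coordinate of the circle center (m), inside the
#'   wall domain.
#' @return A `chord_solution`: list with `tangent_upper`, `tangent_lower`,
#'   `center`, `radius` and `chord_length`.
#' @export
inscribed_circle_at <- function(walls, center_x) {
  stopifnot(inherits(walls, "wall_pair"))
  if (center_x < walls$x_range[1] || center_x > walls$x_range[2])
    stop("center_x outside the wall domain")
  yu <- .wall_y(walls$upper, center_x)
  yl <- .wall_y(walls$lower, center_x)
  g <- function(y) {
    p <- cbind(center_x, y)
    .nearest_upper(walls, p)$dist - .nearest_lower(walls, p)$dist
  }
  root <- stats::uniroot(g, c(yl + 1e-9, yu - 1e-9), tol = 1e-12)
  yc <- root$root
  nu <- .nearest_upper(walls, cbind(center_x, yc))
  nl <- .nearest_lower(walls, cbind(center_x, yc))
  .chord_solution(c(center_x, yc), (nu$dist + nl$dist) / 2,
                  c(nu$x, nu$y), c(nl$x, nl$y))
}

# Perpendicular distance from point p to the chord segments of a centerline
# table (vectorized over stations).
.chord_seg_dist <- function(cl, p) {
  sx <- cl$xl - cl$xu; sy <- cl$yl - cl$yu
  L2 <- pmax(sx * sx + sy * sy, 1e-300)
  tt <- pmin(pmax(((p[1] - cl$xu) * sx + (p[2] - cl$yu) * sy) / L2, 0), 1)
  qx <- cl$xu + tt * sx; qy <- cl$yu + tt * sy
  sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
}

#' Chord (local corridor width) for an agent position
#'
#' Returns the inscribed-circle chord passing through (or, numerically,
#' closest to) the given agent position. The agent's local corridor width is
#' the length of this chord. Ties between chords the agent lies on (possible
#' in symmetric throats) are broken toward the smaller chord, so narrow
#' throats dominate local behaviour.
#'
#' @param walls a [wall_pair()].
#' @param position numeric length-2 agent position, strictly inside the
#'   corridor.
#' @param resolution centerline sampling step (m) used for the initial
#'   discrete search; the cached centerline is reused across calls.
#' @param refine logical; when `TRUE` (default) the discrete solution is
#'   polished by continuous 1-D minimization of the point-to-chord distance
#'   over the centerline parameter.
#' @return A `chord_solution` (see [inscribed_circle_at()]).
#' @export
chord_for_agent <- function(walls, position, resolution = 0.02, refine = TRUE) {
  stopifnot(inherits(walls, "wall_pair"))
  position <- as.numeric(position)
  if (wall_clearance(walls, position)[1] <= 0)
    stop("position is outside the corridor")
  cl <- .centerline_cached(walls, resolution)
  d <- .chord_seg_dist(cl, position)
  dmin <- min(d)
  if (!refine) {
    cand <- which(d <= dmin + 0.5 * resolution)
    j <- cand[which.min(cl$chord[cand])]
    return(.chord_solution(c(cl$x[j], cl$y[j]), cl$radius[j],
                           c(cl$xu[j], cl$yu[j]), c(cl$xl[j], cl$yl[j])))
  }
  # In taper regions several branches of chords may (nearly) contain the
  # agent where chords cross. Refine every candidate branch (discrete local
  # minimum of the point-to-chord distance near the global minimum) by
  # continuous 1-D minimization, keep the branches whose refined chord truly
  # contains the agent, and return the smallest such chord.
  n <- nrow(cl)
  is_locmin <- d <= pmin(c(d[-1], Inf), c(Inf, d[-n])) + 1e-12
  cand <- which(is_locmin & d <= dmin + resolution)
  f <- function(cx) {
    s <- inscribed_circle_at(walls, cx)
    seg <- rbind(s$tangent_upper, s$tangent_lower)
    sx <- seg[2, 1] - seg[1, 1]; sy <- seg[2, 2] - seg[1, 2]
    L2 <- max(sx^2 + sy^2, 1e-300)
    tt <- min(max(((position[1] - seg[1, 1]) * sx +
                     (position[2] - seg[1, 2]) * sy) / L2, 0), 1)
    sqrt((position[1] - (seg[1, 1] + tt * sx))^2 +
           (position[2] - (seg[1, 2] + tt * sy))^2)
  }
  branches <- lapply(cand, function(j) {
    lo <- max(cl$x[max(1L, j - 1L)], walls$x_range[1])
    hi <- min(cl$x[min(n, j + 1L)], walls$x_range[2])
    if (hi <= lo) return(list(dstar = d[j], cx = cl$x[j]))
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-7)
    list(dstar = opt$objective, cx = opt$minimum)
  })
  dstar <- vapply(branches, `[[`, numeric(1), "dstar")
  sols <- lapply(branches, function(b) inscribed_circle_at(walls, b$cx))
  chords <- vapply(sols, `[[`, numeric(1), "chord_length")
  contained <- which(dstar <= 1e-3)
  pick <- if (length(contained)) contained[which.min(chords[contained])]
  else which.min(dstar)
  sols[[pick]]
}

# Project points back to a minimum wall clearance after a position update.
# Points violating the margin (or lying outside the corridor) are placed at
# `margin` from the offending wall, on the corridor side, pushed toward the
# centerline point at the same station.
.project_clearance <- function(walls, P, margin, resolution = 0.02) {
  P <- if (is.matrix(P)) P else matrix(P, ncol = 2)
  eps <- 1e-6
  P[, 1] <- pmin(pmax(P[, 1], walls$x_range[1] + eps),
                 walls$x_range[2] - eps)
  cl <- .centerline_cached(walls, resolution)
  clear <- wall_clearance(walls, P)
  bad <- which(clear < margin)
  for (k in bad) {
    p <- P[k, ]
    cy <- stats::approx(cl$x, cl$y, xout = p[1], rule = 2)$y
    for (side in c("upper", "lower")) {
      nn <- .wall_nearest(walls[[side]], rbind(p), walls$dx,
                          .max_gap(walls) + walls$dx)
      ywall <- .wall_y(walls[[side]], p[1])
      beyond <- if (side == "upper") p[2] >= ywall else p[2] <= ywall
      if (nn$dist < margin || beyond) {
        q <- c(nn$x, nn$y)
        dirv <- c(p[1], cy) - q
        nd <- sqrt(sum(dirv^2))
        if (nd < 1e-12) dirv <- c(0, if (side == "upper") -1 else 1) else dirv <- dirv / nd
        p <- q + margin * dirv
      }
    }
    if (wall_clearance(walls, p)[1] < margin - 1e-9)
      p <- c(p[1], stats::approx(cl$x, cl$y, xout = p[1], rule = 2)$y)
    P[k, ] <- p
  }
  P
}

#' Read or write wall geometry as CSV
#'
#' The interchange format is a plain CSV of `(x, y_upper, y_lower)` samples.
#'
#' @param walls a [wall_pair()].
#' @param path CSV file path.
#' @param dx resampling step used when reading (m).
#' @return `read_walls` returns a [wall_pair()]; `write_walls` returns `path`
#'   invisibly.
#' @export
write_walls <- function(walls, path) {
  utils::write.csv(data.frame(x = walls$upper[, 1],
                              y_upper = walls$upper[, 2],
                              y_lower = walls$lower[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walls
#' @export
read_walls <- function(path, dx = 0.05) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y_upper", "y_lower") %in% names(d)))
    stop("wall CSV must have columns x, y_upper, y_lower")
  wall_pair(cbind(d$x, d$y_upper), cbind(d$x, d$y_lower), dx = dx)
}
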