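# Independent brute-force oracles used to check the geometry solvers.
# These deliberately avoid the package's windowed-segment search and
# bisection: distances are exhaustive over all segments or dense point
# clouds, and the equidistant center is found by staged grid scans.

# Exact distance from a single point to a whole polyline (all segments).
pt_polyline_dist <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  sx <- b[, 1] - a[, 1]
  sy <- b[, 2] - a[, 2]
  tt <- pmin(pmax(((p[1] - a[, 1]) * sx + (p[2] - a[, 2]) * sy) /
                    (sx^2 + sy^2), 0), 1)
  min(sqrt((p[1] - a[, 1] - tt * sx)^2 + (p[2] - a[, 2] - tt * sy)^2))
}

# Dense point cloud on a wall polyline (linear interpolation stays on the
# polyline, so cloud points are exact wall points).
oc_cloud <- function(poly, step) {
  xs <- seq(poly[1, 1], poly[nrow(poly), 1], by = step)
  cbind(xs, stats::approx(poly[, 1], poly[, 2], xout = xs)$y)
}

# Minimum distance from many points to a cloud. Small problems go through a
# dense outer matrix; long station vectors fall back to a running pmin.
oc_cloud_dist <- function(X, Y, cloud) {
  if (length(X) * nrow(cloud) <= 2e6) {
    d2 <- outer(X, cloud[, 1], "-")^2 + outer(Y, cloud[, 2], "-")^2
    jb <- max.col(-d2, ties.method = "first")
    return(sqrt(d2[cbind(seq_along(X), jb)]))
  }
  d2 <- rep(Inf, length(X))
  for (i in seq_len(nrow(cloud)))
    d2 <- pmin(d2, (X - cloud[i, 1])^2 + (Y - cloud[i, 2])^2)
  sqrt(d2)
}

# Nearest cloud point for many query points.
oc_cloud_nearest <- function(X, Y, cloud) {
  d2 <- rep(Inf, length(X))
  ix <- integer(length(X))
  for (i in seq_len(nrow(cloud))) {
    di <- (X - cloud[i, 1])^2 + (Y - cloud[i, 2])^2
    upd <- di < d2
    d2[upd] <- di[upd]
    ix[upd] <- i
  }
  list(d = sqrt(d2), x = cloud[ix, 1], y = cloud[ix, 2])
}

# Staged grid scan for the equidistant (max-inscribed-radius) center on each
# of the given vertical stations, followed by tangent points from the cloud.
oracle_solve_stations <- function(walls, xs, cu, clo) {
  yu <- stats::approx(walls$upper[, 1], walls$upper[, 2], xout = xs)$y
  yl <- stats::approx(walls$lower[, 1], walls$lower[, 2], xout = xs)$y
  gap <- yu - yl
  score_at <- function(y) pmin(oc_cloud_dist(xs, y, cu), oc_cloud_dist(xs, y, clo))
  scan_stage <- function(centers, half_frac, n_steps) {
    best_y <- centers
    best_s <- rep(-Inf, length(xs))
    for (f in seq(-half_frac, half_frac, length.out = n_steps)) {
      y <- pmin(pmax(centers + f * gap, yl + 1e-9), yu - 1e-9)
      s <- score_at(y)
      upd <- s > best_s
      best_s[upd] <- s[upd]
      best_y[upd] <- y[upd]
    }
    best_y
  }
  y1 <- scan_stage((yl + yu) / 2, 0.48, 81)   # step 0.012 * gap
  y2 <- scan_stage(y1, 0.015, 81)             # step 3.75e-4 * gap
  y3 <- scan_stage(y2, 6e-4, 41)              # step 3e-5 * gap
  nu <- oc_cloud_nearest(xs, y3, cu)
  nl <- oc_cloud_nearest(xs, y3, clo)
  data.frame(x = xs, y = y3, radius = (nu$d + nl$d) / 2,
             xu = nu$x, yu = nu$y, xl = nl$x, yl = nl$y,
             chord = sqrt((nu$x - nl$x)^2 + (nu$y - nl$y)^2),
             stringsAsFactors = FALSE)
}

# Chord table over the whole domain, comparable with compute_centerline().
oracle_chord_table <- function(walls, station_step = 0.01, cloud_step = 0.05) {
  cu <- oc_cloud(walls$upper, cloud_step)
  clo <- oc_cloud(walls$lower, cloud_step)
  xs <- seq(walls$x_range[1], walls$x_range[2], by = station_step)
  tab <- oracle_solve_stations(walls, xs, cu, clo)
  attr(tab, "clouds") <- list(cu = cu, clo = clo)
  attr(tab, "station_step") <- station_step
  tab
}

# Polish a coarse tangent point by dense local resampling of the wall.
oracle_refine_tangent <- function(poly, center, x_guess,
                                  halfw = 0.5, step = 0.002) {
  xs <- seq(max(x_guess - halfw, poly[1, 1]),
            min(x_guess + halfw, poly[nrow(poly), 1]), by = step)
  ys <- stats::approx(poly[, 1], poly[, 2], xout = xs)$y
  i <- which.min((center[1] - xs)^2 + (center[2] - ys)^2)
  c(xs[i], ys[i])
}

oc_chord_dist <- function(tab, p) {
  sx <- tab$xl - tab$xu
  sy <- tab$yl - tab$yu
  tt <- pmin(pmax(((p[1] - tab$xu) * sx + (p[2] - tab$yu) * sy) /
                    (sx^2 + sy^2), 0), 1)
  sqrt((p[1] - tab$xu - tt * sx)^2 + (p[2] - tab$yu - tt * sy)^2)
}

# Chord length for an agent. Candidate branches are the discrete local
# minima of the point-to-chord distance; each branch is polished by a fine
# local station scan with tangent points refined on the actual polyline; the
# smallest chord that truly contains the agent wins (nearest branch as a
# fallback), mirroring the solver's declared tie-break.
oracle_chord_for_point <- function(tab, walls, p) {
  step <- attr(tab, "station_step")
  clouds <- attr(tab, "clouds")
  d <- oc_chord_dist(tab, p)
  n <- nrow(tab)
  locmin <- d <= pmin(c(d[-1], Inf), c(Inf, d[-n])) + 1e-12
  cand <- which(locmin & d <= min(d) + step)
  solve_branch <- function(j) {
    xs <- seq(max(tab$x[j] - step, walls$x_range[1]),
              min(tab$x[j] + step, walls$x_range[2]), by = step / 20)
    fine <- oracle_solve_stations(walls, xs, clouds$cu, clouds$clo)
    # de-quantize the cloud tangent points before selecting the station,
    # otherwise chord positions inherit the cloud spacing
    for (k in seq_len(nrow(fine))) {
      ctr <- c(fine$x[k], fine$y[k])
      pu <- oracle_refine_tangent(walls$upper, ctr, fine$xu[k])
      pl <- oracle_refine_tangent(walls$lower, ctr, fine$xl[k])
      fine$xu[k] <- pu[1]; fine$yu[k] <- pu[2]
      fine$xl[k] <- pl[1]; fine$yl[k] <- pl[2]
    }
    fine$chord <- sqrt((fine$xu - fine$xl)^2 + (fine$yu - fine$yl)^2)
    df <- oc_chord_dist(fine, p)
    jf <- which.min(df)
    c(dstar = df[jf], chord = fine$chord[jf])
  }
  res <- vapply(cand, solve_branch, numeric(2))
  contained <- which(res["dstar", ] <= 1e-3)
  if (length(contained))
    min(res["chord", contained])
  else res["chord", which.min(res["dstar", ])]
}

# Small cosine-tapered bottleneck used across geometry tests.
test_bottleneck_walls <- function(length = 12, end_width = 4,
                                  throat_width = 1.4, throat_center = 7,
                                  throat_length = 1.5, taper_length = 2,
                                  dx = 0.02) {
  hw <- function(x) {
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
  wall_pair(function(x) hw(x), function(x) -hw(x), c(0, length), dx = dx)
}

# Random interior points with a clearance buffer, for property tests.
random_interior_points <- function(walls, n, buffer = 0.15) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    x <- stats::runif(n, walls$x_range[1] + buffer, walls$x_range[2] - buffer)
    ymax <- stats::approx(walls$upper[, 1], walls$upper[, 2], xout = x)$y
    ymin <- stats::approx(walls$lower[, 1], walls$lower[, 2], xout = x)$y
    y <- stats::runif(n, ymin, ymax)
    P <- cbind(x, y)
    keep <- wall_clearance(walls, P) > buffer
    out <- rbind(out, P[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
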