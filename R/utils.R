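# Internal helpers: angle arithmetic, regional field interpolation, integer
# apportionment, and point-to-polyline geometry. All angles are degrees,
# measured counterclockwise from the 3 o'clock direction; orientations live
# on [0, 180).

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

wrap360 <- function(a) {
  r <- a %% 360
  r[r >= 360] <- 0 # floating point: (-1e-16) %% 360 == 360
  r
}

wrap180 <- function(a) a %% 180

# Mirror an angle into the orientation half-circle [0, 180). Reflection (not
# modular folding) respects the axial topology of orientation data: a draw
# just below 0 degrees maps to a direction just above 0, never to the far
# side of the half-circle.
reflect180 <- function(a) {
  r <- a %% 360
  r <- ifelse(r > 180, 360 - r, r)
  r %% 180
}

# Largest-remainder apportionment of `total` integer units over weights,
# optionally honouring per-bin integer caps.
largest_remainder <- function(total, weights, cap = NULL) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- q - base
  if (!is.null(cap)) base <- pmin(base, cap)
  left <- total - sum(base)
  out <- base
  ord <- order(rem, decreasing = TRUE)
  k <- 0L
  while (left > 0 && k < 10 * length(weights)) {
    for (i in ord) {
      if (left == 0) break
      if (is.null(cap) || out[i] < cap[i]) {
        out[i] <- out[i] + 1L
        left <- left - 1L
      }
    }
    k <- k + 1L
    if (!is.null(cap) && all(out >= cap)) break
  }
  if (left > 0) {
    abort(sprintf("cannot apportion %d units: capacity exhausted", total))
  }
  as.integer(out)
}

# Piecewise-linear regional field over normalized x in [0, 1]: constant at
# the region anchor inside each quarter, with a linear ramp of half-width
# `delta` across each internal region boundary.
interp_region_field <- function(anchors, xnorm, delta = 0.025) {
  stopifnot(length(anchors) == 4, delta >= 0, delta < 0.125)
  xs <- c(0,
          0.25 - delta, 0.25 + delta,
          0.50 - delta, 0.50 + delta,
          0.75 - delta, 0.75 + delta,
          1)
  vals <- c(anchors[1], anchors[1], anchors[2], anchors[2],
            anchors[3], anchors[3], anchors[4], anchors[4])
  stats::approx(xs, vals, xout = pmin(pmax(xnorm, 0), 1), rule = 2)$y
}

# Minimum Euclidean distance from each point to a polyline (ordered vertex
# table with columns x, y). Vectorised over points, looped over segments.
point_polyline_distance <- function(px, py, poly) {
  stopifnot(nrow(poly) >= 2)
  best <- rep(Inf, length(px))
  x1 <- poly$x[-nrow(poly)]; y1 <- poly$y[-nrow(poly)]
  x2 <- poly$x[-1];          y2 <- poly$y[-1]
  for (s in seq_along(x1)) {
    dx <- x2[s] - x1[s]; dy <- y2[s] - y1[s]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((px - x1[s])^2 + (py - y1[s])^2)
    } else {
      t <- pmin(pmax(((px - x1[s]) * dx + (py - y1[s]) * dy) / len2, 0), 1)
      d <- sqrt((px - (x1[s] + t * dx))^2 + (py - (y1[s] + t * dy))^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Index (along the polyline vertices) of the vertex nearest to each point.
nearest_polyline_vertex <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    which.min((poly$x - px[i])^2 + (poly$y - py[i])^2)
  }, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
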