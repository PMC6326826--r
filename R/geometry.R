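# Band geometry: the enamel_map container, band-local (u, v) coordinates
# (u = arc position along the DEJ from the lateral terminus, micrometres;
# v = normal offset from the DEJ), and the measurement frame operations.
#
# World coordinates are continuous pixel units with x increasing
# lateral -> mesial and y increasing DEJ -> surface (y up). Raster matrices
# are stored in image convention (row 1 = top); pixel (row r, col c) has its
# centre at world (c - 0.5, H - r + 0.5).

#' Build the geometry of a synthetic enamel band
#'
#' Constructs the dentoenamel junction (DEJ), outer-surface and inner/outer
#' layer-boundary polylines for a flat or arc-shaped enamel band, together
#' with the cementoenamel junction (CEJ) endpoints, the raster dimensions
#' and the band bounding box. Layers are left empty; see
#' [render_color_maps()].
#'
#' @param config A [rod_config()].
#' @return An `enamel_map` object: polylines (`dej`, `surface`,
#'   `layer_boundary`; tibbles with `u` in micrometres and world `x`, `y` in
#'   pixels), CEJ endpoints, bounding box, raster dimensions, scale, and an
#'   empty `layers` list.
#' @export
#' @examples
#' geom <- build_band_geometry(rod_config(band_width_um = 120))
#' measure_thickness(geom)
build_band_geometry <- function(config) {
  stopifnot(inherits(config, "rod_config"))
  s <- config$pixels_per_um
  if (s <= 0 || config$thickness_um <= 0) {
    abort("nonpositive thickness or scale")
  }
  W <- config$band_width_um
  Tt <- config$thickness_um
  m <- config$edge_margin_um
  flat <- identical(config$curvature_radius_um, "flat")

  if (flat) {
    frame <- list(type = "flat", margin = m, scale = s, width_um = W,
                  thickness_um = Tt)
  } else {
    R <- config$curvature_radius_um
    phimax <- (W / 2) / R
    if (phimax >= pi / 2) {
      abort("band subtends >= 180 degrees; increase curvature radius")
    }
    cx <- m + (R + Tt) * sin(phimax)
    cy <- m - R * cos(phimax)
    frame <- list(type = "arc", margin = m, scale = s, width_um = W,
                  thickness_um = Tt, radius = R, phimax = phimax,
                  cx = cx, cy = cy)
  }

  du <- 2 # polyline sampling step, micrometres
  us <- unique(c(seq(0, W, by = du), W))
  polyline <- function(v) {
    p <- uv_to_world(frame, us, rep(v, length(us)))
    tibble(u = us, x = p$x, y = p$y)
  }
  dej <- polyline(0)
  surface <- polyline(Tt)
  boundary <- polyline(config$inner_um)

  if (flat) {
    width_px <- ceiling((W + 2 * m) * s)
    height_px <- ceiling((Tt + 2 * m) * s)
  } else {
    width_px <- ceiling(2 * frame$cx * s)
    height_px <- ceiling((frame$cy + frame$radius + Tt + m) * s)
  }
  xs <- c(dej$x, surface$x); ys <- c(dej$y, surface$y)
  cej <- uv_to_world(frame, c(0, W), c(Tt / 2, Tt / 2))

  structure(list(
    width_px = width_px,
    height_px = height_px,
    scale = s,
    frame = frame,
    dej = dej,
    surface = surface,
    layer_boundary = boundary,
    cej_lateral = c(x = cej$x[1], y = cej$y[1]),
    cej_mesial = c(x = cej$x[2], y = cej$y[2]),
    bbox = c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys)),
    inner_um = config$inner_um,
    thickness_um = Tt,
    layers = list(),
    config = config
  ), class = "enamel_map")
}

# Map band-local (u, v) in micrometres to world pixel coordinates.
uv_to_world <- function(frame, u, v) {
  s <- frame$scale
  if (frame$type == "flat") {
    list(x = (frame$margin + u) * s, y = (frame$margin + v) * s)
  } else {
    phi <- (u - frame$width_um / 2) / frame$radius
    list(x = (frame$cx + (frame$radius + v) * sin(phi)) * s,
         y = (frame$cy + (frame$radius + v) * cos(phi)) * s)
  }
}

# Direction of increasing u (the local DEJ-parallel direction), degrees CCW
# from 3 o'clock, at band-local position u.
frame_tangent_deg <- function(frame, u) {
  if (frame$type == "flat") {
    rep(0, length(u))
  } else {
    phi <- (u - frame$width_um / 2) / frame$radius
    -rad2deg(phi)
  }
}

#' @export
print.enamel_map <- function(x, ...) {
  filled <- sum(lengths(lapply(x$layers, dim)) > 0)
  cat(sprintf(
    "<enamel_map> %d x %d px (%g px/um), %s band %g x %g um, %d/4 layers\n",
    x$width_px, x$height_px, x$scale, x$frame$type,
    x$frame$width_um, x$thickness_um, filled))
  invisible(x)
}

#' Append normalized (virtual) coordinates to rod profiles
#'
#' Rescales centroid positions to `[0, 1]` per axis using the min/max
#' bounding rectangle of the enamel layer, so that positions are comparable
#' across maps of different size.
#'
#' @param profiles Tibble with `centroid_x`, `centroid_y` (pixels).
#' @param map An `enamel_map` (its `bbox` supplies the rectangle).
#' @return `profiles` with `norm_x`, `norm_y` columns.
#' @export
normalize_coords <- function(profiles, map) {
  bb <- map$bbox
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"]) {
    abort("degenerate bounding box (zero extent)")
  }
  mutate(profiles,
         norm_x = as.numeric((.data$centroid_x - bb[["xmin"]]) /
                               (bb[["xmax"]] - bb[["xmin"]])),
         norm_y = as.numeric((.data$centroid_y - bb[["ymin"]]) /
                               (bb[["ymax"]] - bb[["ymin"]])))
}

#' Assign the four lateral-to-mesial regions
#'
#' Partitions normalized x into four equally spaced regions, region 1 at the
#' lateral side and region 4 at the mesial side, using half-open bins
#' `[k/4, (k+1)/4)` with the right edge closed at 1.
#'
#' @param norm_x Numeric vector in `[0, 1]`.
#' @return Integer vector of regions 1-4.
#' @export
#' @examples
#' assign_region(c(0, 0.26, 0.5, 1))
assign_region <- function(norm_x) {
  if (any(is.na(norm_x)) || any(norm_x < 0 | norm_x > 1)) {
    abort("norm_x out of range [0, 1]")
  }
  pmin(1L + as.integer(floor(4 * norm_x)), 4L)
}

#' Measure enamel thickness at the point of maximum convexity
#'
#' Locates the most outwardly curved point of the (smoothed) outer-surface
#' polyline - on a flat band, its mid-x point - and measures along the
#' inward surface normal to the DEJ, splitting the distance at the
#' inner/outer layer boundary.
#'
#' @param map An `enamel_map`.
#' @return One-row tibble: `total_um`, `inner_um`, `outer_um`, and the world
#'   pixel coordinates of the measurement site.
#' @export
measure_thickness <- function(map) {
  surf <- map$surface
  n <- nrow(surf)
  if (n < 3) abort("surface polyline too short")
  # smoothed discrete curvature (convexity) along the surface
  k <- 2L
  idx <- (1 + k):(n - k)
  ang <- atan2(surf$y[pmin(idx + k, n)] - surf$y[idx],
               surf$x[pmin(idx + k, n)] - surf$x[idx]) -
         atan2(surf$y[idx] - surf$y[pmax(idx - k, 1)],
               surf$x[idx] - surf$x[pmax(idx - k, 1)])
  ang <- atan2(sin(ang), cos(ang))
  if (max(abs(ang)) < 1e-6) {
    i0 <- which.min(abs(surf$x - mean(range(surf$x)))) # flat: mid-x
  } else {
    # convex outward = clockwise turning; on a constant-curvature arc take
    # the candidate nearest the band midpoint (the apex)
    cand <- idx[-ang >= max(-ang) - 1e-9]
    i0 <- cand[which.min(abs(cand - n / 2))]
  }
  p <- c(surf$x[i0], surf$y[i0])
  i1 <- max(i0 - 1, 1); i2 <- min(i0 + 1, n)
  tangent <- c(surf$x[i2] - surf$x[i1], surf$y[i2] - surf$y[i1])
  nrm <- c(-tangent[2], tangent[1]) / sqrt(sum(tangent^2))
  # orient the normal towards the DEJ
  step <- map$thickness_um * map$scale * 0.05
  d1 <- point_polyline_distance(p[1] + nrm[1] * step, p[2] + nrm[2] * step,
                                map$dej)
  d2 <- point_polyline_distance(p[1] - nrm[1] * step, p[2] - nrm[2] * step,
                                map$dej)
  if (d2 < d1) nrm <- -nrm
  d_dej <- ray_polyline_hit(p, nrm, map$dej)
  d_bnd <- ray_polyline_hit(p, nrm, map$layer_boundary)
  if (!is.finite(d_dej)) abort("surface normal does not intersect the DEJ")
  total <- d_dej / map$scale
  outer <- if (is.finite(d_bnd)) d_bnd / map$scale else NA_real_
  tibble(total_um = total,
         inner_um = total - outer,
         outer_um = outer,
         x_px = p[1], y_px = p[2])
}

# First positive intersection distance of ray (origin p, unit direction d)
# with a polyline; Inf if none.
ray_polyline_hit <- function(p, d, poly) {
  x1 <- poly$x[-nrow(poly)]; y1 <- poly$y[-nrow(poly)]
  x2 <- poly$x[-1];          y2 <- poly$y[-1]
  ex <- x2 - x1; ey <- y2 - y1
  det <- d[1] * (-ey) - d[2] * (-ex)
  ok <- abs(det) > 1e-12
  t <- (( (x1 - p[1]) * (-ey) - (y1 - p[2]) * (-ex) ) / det)
  sseg <- ((d[1] * (y1 - p[2]) - d[2] * (x1 - p[1])) / det)
  hit <- ok & t > 1e-9 & sseg >= -1e-9 & sseg <= 1 + 1e-9
  if (!any(hit)) return(Inf)
  min(t[hit])
}

#' Fractional depth of rod profiles within the enamel layer
#'
#' Perpendicular distance from the DEJ divided by the local total thickness:
#' 0 at the DEJ, 1 at the outer surface.
#'
#' @param profiles Tibble with `centroid_x`, `centroid_y` (pixels) and
#'   (for error reporting) `profile_id`.
#' @param map An `enamel_map`.
#' @param tol_px Tolerance for the inside-band check, pixels.
#' @return `profiles` with a `depth_fraction` column.
#' @export
depth_fraction <- function(profiles, map, tol_px = 2) {
  d_dej <- point_polyline_distance(profiles$centroid_x, profiles$centroid_y,
                                   map$dej)
  d_surf <- point_polyline_distance(profiles$centroid_x, profiles$centroid_y,
                                    map$surface)
  tpx <- map$thickness_um * map$scale
  outside <- d_dej + d_surf > tpx + tol_px
  if (any(outside)) {
    ids <- if ("profile_id" %in% names(profiles)) {
      paste(utils::head(profiles$profile_id[outside], 5), collapse = ", ")
    } else paste(utils::head(which(outside), 5), collapse = ", ")
    abort(sprintf("profiles outside the enamel band: %s", ids))
  }
  mutate(profiles, depth_fraction = d_dej / (d_dej + d_surf))
}

#' Local DEJ tangent direction
#'
#' Total-least-squares line fit of the DEJ polyline over a sliding window
#' centred at the vertex nearest each query point; returns the tangent
#' direction in degrees, mapped to `[0, 180)`.
#'
#' @param x,y Query world coordinates (pixels).
#' @param map An `enamel_map`.
#' @param window_um Window length along the DEJ, micrometres.
#' @return Numeric vector of tangent angles in degrees.
#' @export
dej_tangent_angle <- function(x, y, map, window_um = 50) {
  poly <- map$dej
  half <- max(1L, round(window_um / 2 / max(diff(poly$u)[1], 1e-9)))
  iv <- nearest_polyline_vertex(x, y, poly)
  vapply(iv, function(i) {
    j <- max(1, i - half):min(nrow(poly), i + half)
    px <- poly$x[j] - mean(poly$x[j]); py <- poly$y[j] - mean(poly$y[j])
    v <- eigen(crossprod(cbind(px, py)), symmetric = TRUE)$vectors[, 1]
    wrap180(rad2deg(atan2(v[2], v[1])))
  }, numeric(1))
}

#' Re-express a section-frame angle relative to the DEJ
#'
#' @param angle_section_deg Angle in the plane of section, degrees.
#' @param dej_tangent_deg Local DEJ tangent direction, degrees.
#' @return `(angle - tangent) mod 180`.
#' @export
#' @examples
#' angle_relative_to_dej(10, 30)
angle_relative_to_dej <- function(angle_section_deg, dej_tangent_deg) {
  wrap180(angle_section_deg - dej_tangent_deg)
}
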