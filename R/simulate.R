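# Synthetic enamel-map generation: place rod-profile centroids with known
# category, row membership and orientation, then rasterise them into the
# four color-coded category layers.
#
# Layout model: inner-enamel rows are near-straight chains running from the
# DEJ towards the layer boundary along the local band normal, one chain per
# "lane", lanes alternating mesial/lateral tilt from the lateral to the
# mesial side of the band. Rod orientations (the quantity the pipeline
# measures) are drawn from the regional angle field independently of the
# chain direction. Outer-layer rods sit on short strings of configurable
# nearest-neighbour spacing; CEJ rods form dense patches at the two band
# termini. All placements guarantee a minimum rendered clearance, so the
# rendering -> extraction round trip preserves counts exactly.

#' Sample a full rod-profile layout with ground truth
#'
#' Places every rod profile of a synthetic cross-section and records its
#' generative ground truth: category, tilt, true centroid, true orientation,
#' row membership, region and rendered shape parameters.
#'
#' @param config A [rod_config()].
#' @param geometry An `enamel_map` from [build_band_geometry()].
#' @return Tibble of ground-truth records, one row per rod profile.
#' @export
sample_rod_layout <- function(config, geometry) {
  stopifnot(inherits(config, "rod_config"), inherits(geometry, "enamel_map"))
  set.seed(config$seed)
  targets <- category_targets(config)
  cl_um <- config$clearance_px / config$pixels_per_um
  delta <- config$transition_halfwidth

  inner <- layout_inner(config, geometry, targets[["inner"]], cl_um, delta)
  outer <- layout_outer(config, geometry, targets[["outer"]], cl_um, delta)
  cej <- layout_cej(config, geometry, targets[["cej"]], cl_um, delta)

  out <- bind_rows(inner, outer, cej)
  out$profile_id <- seq_len(nrow(out))
  select(out, "profile_id", dplyr::everything())
}

# normalized x of world points against the band bounding box
band_norm_x <- function(geometry, x) {
  bb <- geometry$bbox
  pmin(pmax((x - bb[["xmin"]]) / (bb[["xmax"]] - bb[["xmin"]]), 0), 1)
}

# draw orientation angles: regional field mean/sd at norm_x, normal noise
# reflected into [0, 180); optionally anchored in the DEJ-parallel frame
draw_angles <- function(config, field, norm_x, u, frame) {
  mu <- interp_region_field(field$mean, norm_x, config$transition_halfwidth)
  sdv <- interp_region_field(field$sd, norm_x, config$transition_halfwidth)
  a <- reflect180(mu + sdv * rnorm(length(norm_x)))
  if (config$angle_frame == "dej") {
    a <- wrap180(a + frame_tangent_deg(frame, u))
  }
  a
}

layout_inner <- function(config, geometry, n_inner, cl_um, delta) {
  frame <- geometry$frame
  W <- config$band_width_um
  a_semi <- config$shapes$ellipse_axes_um[["long"]] / 2
  v_margin <- a_semi + cl_um + config$jitter$start_um
  usable <- config$inner_um - 2 * v_margin
  if (usable <= 0) abort("inner layer too thin for the configured rod size")

  n_lanes <- config$n_rows
  pitch <- (W - 2 * config$lane_margin_um) / n_lanes
  u_lane <- config$lane_margin_um + pitch * (seq_len(n_lanes) - 0.5)
  tilt <- ifelse(seq_len(n_lanes) %% 2 == 1, "mesial", "lateral")
  mid <- uv_to_world(frame, u_lane, rep(config$inner_um / 2, n_lanes))
  nx_lane <- band_norm_x(geometry, mid$x)

  jsp <- config$jitter$spacing
  spacing <- numeric(n_lanes)
  for (tl in c("mesial", "lateral")) {
    f <- config$spacing_field[[paste0("inner_", tl)]]
    idx <- tilt == tl
    spacing[idx] <- interp_region_field(f, nx_lane[idx], delta)
  }
  capacity <- pmax(floor(usable / (spacing * (1 + jsp))), 0) + 1L
  if (sum(capacity) < n_inner) {
    lim <- assign_region(nx_lane[which.min(capacity)])
    abort(sprintf(
      "cannot place %d inner profiles (capacity %d); limiting region: %d",
      n_inner, sum(capacity), lim))
  }
  rpr <- largest_remainder(n_inner, capacity, cap = capacity)

  lanes <- lapply(seq_len(n_lanes), function(i) {
    k <- rpr[i]
    if (k == 0) return(NULL)
    v0 <- v_margin + runif(1, -1, 1) * config$jitter$start_um
    gaps <- spacing[i] * (1 + runif(max(k - 1, 0), -jsp, jsp))
    v <- v0 + c(0, cumsum(gaps))
    u <- u_lane[i] + runif(k, -1, 1) * config$jitter$lateral_um
    p <- uv_to_world(frame, u, v)
    nx <- band_norm_x(geometry, p$x)
    field <- config$angle_field[[paste0("inner_", tilt[i])]]
    tibble(
      category = paste0("inner_", tilt[i]),
      tilt = tilt[i],
      true_x_px = p$x, true_y_px = p$y,
      u_um = u, v_um = v,
      true_angle_deg = draw_angles(config, field, nx, u, frame),
      true_row_id = i,
      true_seq_index = seq_len(k),
      region = assign_region(nx),
      shape = "ellipse",
      size1_um = config$shapes$ellipse_axes_um[["long"]],
      size2_um = config$shapes$ellipse_axes_um[["short"]],
      exponent = 2
    )
  })
  list_rbind(lanes)
}

layout_outer <- function(config, geometry, n_outer, cl_um, delta) {
  if (n_outer == 0) return(NULL)
  frame <- geometry$frame
  W <- config$band_width_um
  d_semi <- config$shapes$rhombus_diag_um[["long"]] / 2
  v_margin <- d_semi + cl_um
  usable_v <- config$outer_um - 2 * v_margin
  if (usable_v <= 0) abort("outer layer too thin for the configured rod size")
  n_strings <- 6L
  v_levels <- config$inner_um + v_margin +
    usable_v * (seq_len(n_strings) - 0.5) / n_strings

  # region u-intervals clipped to the string span
  u_lo <- config$lane_margin_um
  u_hi <- W - config$lane_margin_um
  breaks <- seq(0, W, length.out = 5)
  spac <- config$spacing_field$outer
  jsp <- config$jitter$spacing

  # apportion across regions by linear density, capped by string capacity
  lens <- pmax(pmin(breaks[-1], u_hi) - pmax(breaks[-5], u_lo), 0)
  capacity <- vapply(1:4, function(r) {
    n_strings * max(floor(lens[r] / (spac[r] * (1 + jsp))), 0)
  }, numeric(1))
  if (sum(capacity) < n_outer) {
    abort(sprintf(
      "cannot place %d outer profiles (capacity %d); limiting region: %d",
      n_outer, sum(capacity), which.min(capacity / pmax(lens, 1e-9))))
  }
  per_region <- largest_remainder(n_outer, lens / spac, cap = capacity)

  regions <- lapply(1:4, function(r) {
    k <- per_region[r]
    if (k == 0) return(NULL)
    cap_s <- max(floor(lens[r] / (spac[r] * (1 + jsp))), 0)
    per_string <- largest_remainder(k, rep(1, n_strings),
                                    cap = rep(cap_s, n_strings))
    strings <- lapply(seq_len(n_strings), function(j) {
      m <- per_string[j]
      if (m == 0) return(NULL)
      gaps <- spac[r] * (1 + runif(max(m - 1, 0), -jsp, jsp))
      span <- sum(gaps)
      u0 <- pmax(breaks[r], u_lo) + (lens[r] - span) / 2
      u <- u0 + c(0, cumsum(gaps))
      v <- v_levels[j] + runif(m, -0.15, 0.15)
      p <- uv_to_world(frame, u, v)
      nx <- band_norm_x(geometry, p$x)
      tibble(
        category = "outer", tilt = NA_character_,
        true_x_px = p$x, true_y_px = p$y, u_um = u, v_um = v,
        true_angle_deg = draw_angles(config, config$angle_field$outer,
                                     nx, u, frame),
        true_row_id = NA_integer_, true_seq_index = NA_integer_,
        region = assign_region(nx),
        shape = "rhombus",
        size1_um = config$shapes$rhombus_diag_um[["long"]],
        size2_um = config$shapes$rhombus_diag_um[["short"]],
        exponent = 1
      )
    })
    list_rbind(strings)
  })
  list_rbind(regions)
}

layout_cej <- function(config, geometry, n_cej, cl_um, delta) {
  if (n_cej == 0) return(NULL)
  frame <- geometry$frame
  W <- config$band_width_um
  a_max <- max(config$shapes$cej_axes_um$long) / 2
  g <- config$spacing_field$cej[1] # patch grid pitch
  v_margin <- a_max + cl_um
  v_lo <- v_margin; v_hi <- config$thickness_um - v_margin
  n_v <- max(floor((v_hi - v_lo) / g), 1)
  split <- largest_remainder(n_cej, c(config$cej_mesial_fraction,
                                      1 - config$cej_mesial_fraction))
  n_cols_max <- max(floor((config$lane_margin_um - 2 - 2 * a_max) / g), 1)
  if (n_cols_max * n_v < max(split)) {
    abort(sprintf(
      "cannot place %d CEJ profiles (capacity %d); limiting region: %d",
      max(split), n_cols_max * n_v, if (which.max(split) == 1) 4L else 1L))
  }
  ends <- list(
    mesial = list(n = split[1], u0 = W - 2 - a_max, dir = -1),
    lateral = list(n = split[2], u0 = 2 + a_max, dir = +1)
  )
  out <- lapply(ends, function(e) {
    if (e$n == 0) return(NULL)
    ncol_used <- ceiling(e$n / n_v)
    cells <- expand.grid(col = seq_len(ncol_used), rowv = seq_len(n_v))
    cells <- cells[order(cells$col, cells$rowv), ][seq_len(e$n), ]
    u <- e$u0 + e$dir * (cells$col - 0.5) * g + runif(e$n, -0.15, 0.15)
    v <- v_lo + (cells$rowv - 0.5) * ((v_hi - v_lo) / n_v) +
      runif(e$n, -0.15, 0.15)
    p <- uv_to_world(frame, u, v)
    nx <- band_norm_x(geometry, p$x)
    tibble(
      category = "cej", tilt = NA_character_,
      true_x_px = p$x, true_y_px = p$y, u_um = u, v_um = v,
      true_angle_deg = draw_angles(config, config$angle_field$cej,
                                   nx, u, frame),
      true_row_id = NA_integer_, true_seq_index = NA_integer_,
      region = assign_region(nx),
      shape = "blob",
      size1_um = runif(e$n, config$shapes$cej_axes_um$long[1],
                       config$shapes$cej_axes_um$long[2]),
      size2_um = runif(e$n, config$shapes$cej_axes_um$short[1],
                       config$shapes$cej_axes_um$short[2]),
      exponent = runif(e$n, config$shapes$cej_exponent[1],
                       config$shapes$cej_exponent[2])
    )
  })
  list_rbind(out)
}

#' Rasterise ground-truth records into the four category layers
#'
#' Fills one binary raster layer per rod category (inner-mesial,
#' inner-lateral, outer, CEJ) from the ground-truth records. Every record
#' becomes a single filled connected region; an occupancy check guarantees
#' no two records share a pixel.
#'
#' @param records Ground-truth tibble from [sample_rod_layout()].
#' @param geometry An `enamel_map` (geometry only).
#' @return The `enamel_map` with `layers` filled (logical matrices in image
#'   convention, row 1 = top) and the records attached as `truth`.
#' @export
render_color_maps <- function(records, geometry) {
  H <- geometry$height_px; W <- geometry$width_px
  s <- geometry$scale
  layers <- lapply(ROD_CATEGORIES, function(cat) {
    matrix(FALSE, nrow = H, ncol = W)
  })
  names(layers) <- ROD_CATEGORIES
  occupancy <- matrix(0L, nrow = H, ncol = W)

  if (!is.null(records) && nrow(records) > 0) {
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      px <- shape_pixels(rec, s, H, W)
      if (is.null(px)) {
        abort(sprintf("record %s renders outside the image",
                      rec$profile_id %||% i))
      }
      idx <- (px$col - 1L) * H + px$row
      hit <- occupancy[idx]
      if (any(hit != 0L)) {
        abort(sprintf("records %d and %d overlap when rendered",
                      hit[hit != 0L][1], i))
      }
      occupancy[idx] <- i
      layers[[rec$category]][idx] <- TRUE
    }
  }
  geometry$layers <- layers
  geometry$truth <- records
  geometry
}

# pixel (row, col) set of one rendered record; NULL if out of image bounds
shape_pixels <- function(rec, scale, H, W) {
  a <- rec$size1_um / 2 * scale
  b <- rec$size2_um / 2 * scale
  th <- deg2rad(rec$true_angle_deg)
  ext <- max(a, b) + 1
  cx <- rec$true_x_px; cy <- rec$true_y_px
  cols <- (floor(cx - ext) + 1L):(floor(cx + ext) + 1L)
  # world y of raster rows: y = H - r + 0.5
  ylo <- cy - ext; yhi <- cy + ext
  rows <- (floor(H - yhi + 0.5) + 1L):(floor(H - ylo + 0.5))
  if (min(cols) < 1 || max(cols) > W || min(rows) < 1 || max(rows) > H) {
    return(NULL)
  }
  g <- expand.grid(row = rows, col = cols)
  dx <- (g$col - 0.5) - cx
  dy <- (H - g$row + 0.5) - cy
  up <- dx * cos(th) + dy * sin(th)
  vp <- -dx * sin(th) + dy * cos(th)
  inside <- switch(rec$shape,
    ellipse = (up / a)^2 + (vp / b)^2 <= 1,
    rhombus = abs(up) / a + abs(vp) / b <= 1,
    blob = (abs(up) / a)^rec$exponent + (abs(vp) / b)^rec$exponent <= 1,
    abort(sprintf("unknown shape '%s'", rec$shape))
  )
  if (!any(inside)) { # guarantee at least the centre pixel
    ctr <- g[which.min(dx^2 + dy^2), , drop = FALSE]
    return(list(row = ctr$row, col = ctr$col))
  }
  list(row = g$row[inside], col = g$col[inside])
}

#' Simulate a complete synthetic enamel map
#'
#' Convenience wrapper: build the band geometry, sample the rod layout and
#' render the category layers in one seeded call.
#'
#' @param config A [rod_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An `enamel_map` with filled layers and a `truth` tibble.
#' @export
#' @examples
#' \donttest{
#' map <- simulate_enamel_map(rod_config(total_profiles = 200, n_rows = 6,
#'                                       band_width_um = 80))
#' nrow(map$truth)
#' }
simulate_enamel_map <- function(config, seed = NULL) {
  stopifnot(inherits(config, "rod_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  geometry <- build_band_geometry(config)
  records <- sample_rod_layout(config, geometry)
  render_color_maps(records, geometry)
}
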