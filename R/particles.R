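# The measurement core: thresholding, 8-connected particle labeling, and
# per-particle morphometrics (area, centroid, long/short Feret diameters and
# Feret angle) with the classic particle-analysis conventions: angles in
# degrees counterclockwise from the 3 o'clock direction, mapped to [0, 180).

#' Threshold a grayscale layer into a binary mask
#'
#' @param layer_image Single-channel numeric matrix (0-1 grayscale as read
#'   by [png::readPNG()], or any numeric range), or a logical matrix (then
#'   returned unchanged, making the operation idempotent on binary input).
#' @param threshold Intensity cut-off (same units as the image).
#' @param dark_foreground If `TRUE` (default), pixels strictly below the
#'   threshold are foreground - rod profiles are rendered dark on a light
#'   background.
#' @return Logical matrix mask.
#' @export
threshold_layer <- function(layer_image, threshold = 0.5,
                            dark_foreground = TRUE) {
  if (length(layer_image) == 0) abort("empty image")
  if (is.logical(layer_image)) return(layer_image)
  if (!is.matrix(layer_image)) abort("layer image must be a single-channel matrix")
  if (dark_foreground) layer_image < threshold else layer_image >= threshold
}

#' Label connected particles in a binary mask
#'
#' One label per 8-connected foreground component, labels contiguous from 1.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer label matrix with attribute `n` (component count).
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' attr(extract_particles(m), "n")
extract_particles <- function(mask) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  storage.mode(mask) <- "logical"
  .cc_label8(mask)
}

#' Measure particle morphometrics
#'
#' Computes, for each labeled particle: pixel area, centroid (mean of pixel
#' centres, world coordinates with y up), and Feret statistics from the
#' convex hull of the pixel corners - `feret_max` is the maximum caliper
#' width (the hull diameter), `feret_min` the minimum caliper width over all
#' orientations (rotating calipers over hull edges), and `feret_angle_deg`
#' the orientation of the maximum-Feret support direction in degrees
#' counterclockwise from 3 o'clock, mapped to `[0, 180)`. Exactly tied
#' maximal chords resolve to the axial mean of the tied directions (so a
#' vertically symmetric particle measures exactly vertical); antipodal tie
#' sets with no defined axial mean, such as the two diagonals of a square,
#' fall back to the smallest angle. Building the hull on pixel corners (not centres)
#' gives a 1x1 px particle `feret_max = sqrt(2)` and `feret_min = 1`.
#'
#' @param labels Label matrix from [extract_particles()].
#' @param ids Optional particle ids to measure (default: all); unknown ids
#'   are an error.
#' @return Tibble: `particle_id`, `area_px2`, `centroid_x`, `centroid_y`,
#'   `feret_max_px`, `feret_min_px`, `feret_angle_deg`.
#' @export
measure_particles <- function(labels, ids = NULL) {
  H <- nrow(labels)
  fg <- which(labels > 0L)
  lab <- labels[fg]
  n <- attr(labels, "n") %||% if (length(lab)) max(lab) else 0L
  if (!is.null(ids)) {
    if (length(ids) == 0 || any(ids < 1L | ids > n)) {
      abort("unknown particle id")
    }
  } else {
    ids <- seq_len(n)
  }
  if (n == 0L || length(fg) == 0L) {
    return(tibble(particle_id = integer(), area_px2 = numeric(),
                  centroid_x = numeric(), centroid_y = numeric(),
                  feret_max_px = numeric(), feret_min_px = numeric(),
                  feret_angle_deg = numeric()))
  }
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  xs <- cols - 0.5
  ys <- H - rows + 0.5
  ord <- order(lab)
  lab <- lab[ord]; xs <- xs[ord]; ys <- ys[ord]
  bounds <- c(0L, cumsum(tabulate(lab, nbins = n)))

  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    sel <- (bounds[id] + 1L):bounds[id + 1L]
    f <- feret_stats(xs[sel], ys[sel])
    out[[k]] <- c(id, length(sel), mean(xs[sel]), mean(ys[sel]),
                  f[1], f[2], f[3])
  }
  m <- do.call(rbind, out)
  tibble(particle_id = as.integer(m[, 1]), area_px2 = m[, 2],
         centroid_x = m[, 3], centroid_y = m[, 4],
         feret_max_px = m[, 5], feret_min_px = m[, 6],
         feret_angle_deg = m[, 7])
}

# Feret statistics of one pixel set (centres xs, ys): hull on pixel corners,
# diameter by antipodal pairs, min width by rotating calipers over edges.
feret_stats <- function(xs, ys) {
  cx <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  h <- grDevices::chull(cx, cy)
  hx <- cx[h]; hy <- cy[h]
  m <- length(hx)
  if (m == 1) return(c(sqrt(2), 1, 0)) # cannot happen for corner hulls
  dx <- outer(hx, hx, "-"); dy <- outer(hy, hy, "-")
  d2 <- dx^2 + dy^2
  dmax2 <- max(d2)
  # all diameter-achieving chords: exact ties are resolved to the axial
  # (doubled-angle) mean of the tied directions, which is unbiased for
  # near-symmetric particles; antipodal tie sets whose axial mean is
  # undefined (e.g. the two diagonals of a square) fall back to the
  # smallest angle
  pairs <- which(d2 >= dmax2 - 1e-9, arr.ind = TRUE)
  angs <- unique(round(wrap180(rad2deg(atan2(dy[pairs], dx[pairs]))), 9))
  if (length(angs) == 1) {
    feret_angle <- angs
  } else {
    s2 <- mean(sin(deg2rad(2 * angs))); c2 <- mean(cos(deg2rad(2 * angs)))
    if (sqrt(s2^2 + c2^2) > 0.5) {
      feret_angle <- wrap180(rad2deg(atan2(s2, c2)) / 2)
    } else {
      feret_angle <- min(angs)
    }
  }
  # min caliper width: for each hull edge, the farthest vertex distance
  if (m == 2) {
    fmin <- 0
  } else {
    ex <- hx[c(2:m, 1)] - hx; ey <- hy[c(2:m, 1)] - hy
    elen <- sqrt(ex^2 + ey^2)
    keep <- elen > 1e-12
    widths <- vapply(which(keep), function(e) {
      max(abs((hx - hx[e]) * (-ey[e]) + (hy - hy[e]) * ex[e]) / elen[e])
    }, numeric(1))
    fmin <- min(widths)
  }
  c(sqrt(dmax2), fmin, feret_angle)
}

#' Convert pixel morphometrics to micrometres
#'
#' Divides lengths by `pixels_per_um` and areas by its square, appending
#' `*_um` columns while retaining the pixel fields.
#'
#' @param profiles Tibble with pixel-unit columns (`area_px2`,
#'   `feret_max_px`, `feret_min_px`, and optionally `centroid_x`/`_y`).
#' @param pixels_per_um Positive scale factor.
#' @return `profiles` with `area_um2`, `feret_max_um`, `feret_min_um`,
#'   `centroid_x_um`, `centroid_y_um` columns.
#' @export
#' @examples
#' to_micrometers(tibble::tibble(area_px2 = 400, feret_max_px = 100,
#'                               feret_min_px = 50), 2)
to_micrometers <- function(profiles, pixels_per_um) {
  if (pixels_per_um <= 0) abort("pixels_per_um must be positive")
  s <- pixels_per_um
  out <- profiles
  if ("area_px2" %in% names(out)) out$area_um2 <- out$area_px2 / s^2
  for (f in c("feret_max", "feret_min")) {
    px <- paste0(f, "_px")
    if (px %in% names(out)) out[[paste0(f, "_um")]] <- out[[px]] / s
  }
  for (f in c("centroid_x", "centroid_y")) {
    if (f %in% names(out)) out[[paste0(f, "_um")]] <- out[[f]] / s
  }
  out
}
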