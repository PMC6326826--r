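# Circular statistics of rod orientation data. Tilt angles are treated as
# directions on [0, 360) fed with values in [0, 180): the plain (not
# axial-doubled) circular mean, matching the convention under which the
# mean of {30, 60, 80} degrees is 57 degrees to the nearest degree.

#' Circular mean, resultant length and circular SD
#'
#' Mean direction from the `atan2` of the mean sine and cosine, mapped to
#' `[0, 360)`; resultant length is the norm of the mean unit vector;
#' circular SD is `sqrt(-2 ln R)` (radians, reported in degrees).
#'
#' @param angles_deg Nonempty numeric vector of angles in degrees.
#' @return One-row tibble: `n`, `mean_deg`, `circular_sd_deg`,
#'   `resultant_length`.
#' @export
#' @examples
#' circular_mean(c(30, 60, 80)) # mean 56.8, i.e. 57 to the nearest degree
circular_mean <- function(angles_deg) {
  if (length(angles_deg) == 0 || all(is.na(angles_deg))) {
    abort("circular_mean needs at least one angle")
  }
  a <- deg2rad(angles_deg[!is.na(angles_deg)])
  s <- mean(sin(a)); c <- mean(cos(a))
  r <- min(sqrt(s^2 + c^2), 1)
  tibble(
    n = length(a),
    mean_deg = wrap360(rad2deg(atan2(s, c))),
    circular_sd_deg = if (r > 0) rad2deg(sqrt(-2 * log(r))) else Inf,
    resultant_length = r
  )
}

#' Decussation angle from two mean directions
#'
#' The smallest absolute angular difference between the mesial-tilt and
#' lateral-tilt mean directions, in `[0, 180]`.
#'
#' @param mean_mesial_deg,mean_lateral_deg Mean directions in degrees.
#' @return Angle in degrees.
#' @export
#' @examples
#' decussation_from_means(104, 49) # 55
decussation_from_means <- function(mean_mesial_deg, mean_lateral_deg) {
  d <- abs(wrap360(mean_mesial_deg) - wrap360(mean_lateral_deg)) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Alternating inter-row angle
#'
#' The wide angle formed where two rows of opposite tilt abut: 180 degrees
#' minus the decussation angle of the pair, labeled by the transition
#' direction.
#'
#' @param row_a,row_b One-row tibbles (or lists) with `tilt` and `mean_deg`.
#' @param transition `"mesial_to_lateral"` or `"lateral_to_mesial"`; by
#'   default inferred from the tilt of `row_a`.
#' @return One-row tibble: `transition`, `decussation_deg`,
#'   `inter_row_angle_deg`.
#' @export
inter_row_angle <- function(row_a, row_b, transition = NULL) {
  if (is.na(row_a$tilt) || is.na(row_b$tilt) || row_a$tilt == row_b$tilt) {
    abort("inter-row angle requires a pair of opposite tilts")
  }
  transition <- transition %||%
    if (row_a$tilt == "mesial") "mesial_to_lateral" else "lateral_to_mesial"
  dec <- decussation_from_means(
    if (row_a$tilt == "mesial") row_a$mean_deg else row_b$mean_deg,
    if (row_a$tilt == "lateral") row_a$mean_deg else row_b$mean_deg)
  tibble(transition = transition, decussation_deg = dec,
         inter_row_angle_deg = 180 - dec)
}

#' Nearest-neighbour distance of every centroid
#'
#' Exact distance from each point to its closest other point (grid-indexed
#' search).
#'
#' @param centroids Tibble/data frame with `x` and `y` columns, or a
#'   two-column matrix; at least two points.
#' @return Numeric vector of per-point nearest-neighbour distances.
#' @export
nearest_neighbor_distances <- function(centroids) {
  if (is.matrix(centroids)) {
    x <- centroids[, 1]; y <- centroids[, 2]
  } else {
    x <- centroids$x %||% centroids$centroid_x
    y <- centroids$y %||% centroids$centroid_y
  }
  if (length(x) < 2) abort("need at least 2 points")
  .nn_dist(as.numeric(x), as.numeric(y))
}

#' Euclidean distance between two centroids
#'
#' @param p1,p2 Length-2 numeric vectors `(x, y)`, or two-column matrices of
#'   paired coordinates.
#' @return Distance(s).
#' @export
#' @examples
#' inter_centroid_distance(c(0, 0), c(3, 4)) # 5
inter_centroid_distance <- function(p1, p2) {
  if (is.matrix(p1) || is.data.frame(p1)) {
    sqrt((p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2)
  } else {
    sqrt(sum((p1 - p2)^2))
  }
}
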