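# Row-pair angle statistics (decussation and alternating inter-row angles),
# spacing/packing summaries, category composition, and distance-weighted
# least-squares surface smoothing for visualisation.

#' Decussation angles between depth-adjacent alternating rows
#'
#' Walks rows in `row_id` order and, for every adjacent pair of opposite
#' tilt, computes the decussation angle between the two rows' circular mean
#' directions and its supplement, the alternating inter-row angle. Adjacent
#' pairs sharing a tilt are skipped and reported in the `skipped_pairs`
#' attribute.
#'
#' @param rows Per-row tibble from [summarize_rows()] (needs `row_id`,
#'   `tilt`, `mean_deg`, `region`).
#' @param by_region Also return a per-region summary as the `regional`
#'   attribute.
#' @return Tibble of pairs: `row_a`, `row_b`, `transition`, `region`
#'   (region of the pair, from the mean midpoint), `decussation_deg`,
#'   `inter_row_angle_deg`. Fewer than 2 rows give an empty result.
#' @export
decussation_by_rows <- function(rows, by_region = TRUE) {
  rows <- arrange(rows, .data$row_id)
  n <- nrow(rows)
  if (n < 2) {
    out <- tibble(row_a = integer(), row_b = integer(),
                  transition = character(), region = integer(),
                  decussation_deg = numeric(),
                  inter_row_angle_deg = numeric())
    attr(out, "skipped_pairs") <- 0L
    return(out)
  }
  a <- rows[-n, ]; b <- rows[-1, ]
  alternating <- !is.na(a$tilt) & !is.na(b$tilt) & a$tilt != b$tilt
  skipped <- sum(!alternating)
  if (skipped > 0) {
    warn(sprintf("%d non-alternating adjacent row pair(s) skipped", skipped))
  }
  mes <- ifelse(a$tilt == "mesial", a$mean_deg, b$mean_deg)
  lat <- ifelse(a$tilt == "lateral", a$mean_deg, b$mean_deg)
  dec <- decussation_from_means(mes, lat)
  out <- tibble(
    row_a = a$row_id, row_b = b$row_id,
    transition = ifelse(a$tilt == "mesial", "mesial_to_lateral",
                        "lateral_to_mesial"),
    region = as.integer(round((a$region + b$region) / 2)),
    decussation_deg = dec,
    inter_row_angle_deg = 180 - dec
  )[alternating, ]
  if (by_region) {
    attr(out, "regional") <- out |>
      group_by(.data$region) |>
      summarise(n_pairs = dplyr::n(),
                decussation_mean_deg = mean(.data$decussation_deg),
                decussation_sd_deg = sd(.data$decussation_deg),
                inter_row_mean_deg = mean(.data$inter_row_angle_deg),
                inter_row_sd_deg = sd(.data$inter_row_angle_deg),
                .groups = "drop")
  }
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Regional decussation from grand means and from row pairs, side by side
#'
#' The decussation angle per region computed two ways: from the regional
#' grand mean directions of the two tilt categories, and as the mean of
#' row-by-row angle differences between depth-adjacent alternating rows.
#'
#' @param profiles Per-rod tibble with `tilt`, `region`, `feret_angle_deg`
#'   (inner categories only are used).
#' @param pairs Pair table from [decussation_by_rows()].
#' @return Tibble keyed by region with `decussation_from_grand_means_deg`
#'   and `decussation_rowwise_mean_deg` (+SD, n).
#' @export
decussation_regional <- function(profiles, pairs) {
  inner <- filter(profiles, .data$tilt %in% c("mesial", "lateral"))
  grand <- inner |>
    group_by(.data$region, .data$tilt) |>
    summarise(mean_deg = circular_mean(.data$feret_angle_deg)$mean_deg,
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tilt", values_from = "mean_deg") |>
    mutate(decussation_from_grand_means_deg =
             decussation_from_means(.data$mesial, .data$lateral))
  roww <- pairs |>
    group_by(.data$region) |>
    summarise(n_pairs = dplyr::n(),
              decussation_rowwise_mean_deg = mean(.data$decussation_deg),
              decussation_rowwise_sd_deg = sd(.data$decussation_deg),
              .groups = "drop")
  left_join(grand, roww, by = "region")
}

#' Spacing summary by category, tilt and region
#'
#' Inner-enamel spacing is the within-row sequential inter-centroid
#' distance (each gap assigned to the region of the gap midpoint); outer
#' and CEJ spacing are nearest-neighbour distances grouped by region.
#' Means and SDs are reported in micrometres. Empty groups are absent from
#' the table, not zero.
#'
#' @param profiles Per-rod tibble with `category`, `tilt`, `row_id`,
#'   `seq_index`, `centroid_x`, `centroid_y`, `region`, `norm_x`.
#' @param pixels_per_um Scale.
#' @return Tibble: `category`, `tilt`, `region`, `n`, `spacing_mean_um`,
#'   `spacing_sd_um`.
#' @export
spacing_summary <- function(profiles, pixels_per_um) {
  s <- pixels_per_um
  inner <- profiles |>
    filter(.data$category %in% c("inner_mesial", "inner_lateral"),
           !is.na(.data$row_id)) |>
    arrange(.data$row_id, .data$seq_index)
  gaps <- NULL
  if (nrow(inner) > 1) {
    same_row <- inner$row_id[-1] == inner$row_id[-nrow(inner)]
    d <- sqrt(diff(inner$centroid_x)^2 + diff(inner$centroid_y)^2) / s
    midnx <- (inner$norm_x[-1] + inner$norm_x[-nrow(inner)]) / 2
    gaps <- tibble(
      category = inner$category[-1][same_row],
      tilt = inner$tilt[-1][same_row],
      region = assign_region(midnx[same_row]),
      d = d[same_row]
    )
  }
  oc <- filter(profiles, .data$category %in% c("outer", "cej"))
  nn <- list_rbind(lapply(split(oc, oc$category), function(df) {
    if (nrow(df) < 2) return(NULL)
    tibble(category = df$category, tilt = df$tilt, region = df$region,
           d = nearest_neighbor_distances(
             cbind(df$centroid_x, df$centroid_y)) / s)
  }))
  if (is.null(gaps) && (is.null(nn) || nrow(nn) == 0)) {
    return(tibble(category = character(), tilt = character(),
                  region = integer(), n = integer(),
                  spacing_mean_um = numeric(), spacing_sd_um = numeric()))
  }
  bind_rows(gaps, nn) |>
    group_by(.data$category, .data$tilt, .data$region) |>
    summarise(n = dplyr::n(),
              spacing_mean_um = mean(.data$d),
              spacing_sd_um = sd(.data$d), .groups = "drop")
}

#' Category composition of a cross-section
#'
#' Integer counts per rod category with percentages rounded to the nearest
#' integer (matching the precision such composition tables are reported
#' at), plus rows-per-tilt counts when a row table is supplied.
#'
#' @param profiles Per-rod tibble with `category` (and `tilt`).
#' @param rows Optional per-row tibble with `tilt`.
#' @return Tibble: `category`, `n`, `percent`; attribute `rows_per_tilt`
#'   when `rows` is given.
#' @export
#' @examples
#' category_counts(tibble::tibble(category = rep(c("inner_mesial", "outer"),
#'                                               c(7, 3))))
category_counts <- function(profiles, rows = NULL) {
  total <- nrow(profiles)
  out <- profiles |>
    group_by(.data$category) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    mutate(percent = if (total > 0) round(100 * n / total) else NA_real_)
  if (!is.null(rows)) {
    attr(out, "rows_per_tilt") <- rows |>
      group_by(.data$tilt) |>
      summarise(n_rows = dplyr::n(), .groups = "drop")
  }
  out
}

#' Distance-weighted least-squares surface
#'
#' Smooths scattered `(x, y, value)` data onto a regular grid by locally
#' weighted linear regression with Gaussian distance weights - the smoothing
#' used for angle-field surface plots. Exact on planar inputs.
#'
#' @param points Tibble/data frame with `x`, `y`, `value`.
#' @param n_grid Grid nodes per axis.
#' @param bandwidth Gaussian kernel SD as a fraction of the larger data
#'   range; must be positive.
#' @return Tibble grid: `x`, `y`, `value`.
#' @export
dwls_surface <- function(points, n_grid = 25, bandwidth = 0.25) {
  if (bandwidth <= 0) abort("bandwidth must be positive")
  if (nrow(points) < 10) abort("need at least 10 points")
  rx <- range(points$x); ry <- range(points$y)
  h <- bandwidth * max(diff(rx), diff(ry))
  gx <- seq(rx[1], rx[2], length.out = n_grid)
  gy <- seq(ry[1], ry[2], length.out = n_grid)
  grid <- expand.grid(x = gx, y = gy)
  X <- cbind(1, points$x, points$y)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    w <- exp(-((points$x - grid$x[i])^2 + (points$y - grid$y[i])^2) /
               (2 * h^2))
    w <- w + 1e-12
    fit <- stats::lm.wfit(X, points$value, w)
    sum(c(1, grid$x[i], grid$y[i]) * fit$coefficients)
  }, numeric(1))
  tibble(x = grid$x, y = grid$y, value = vals)
}
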