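# Automated assembly of inner-enamel rod rows. The reference workflow
# outlined each row by hand with an irregular polygon; here profiles of one
# tilt category are chained to their nearest same-category neighbours within
# a gating distance, chains become rows, and rows are numbered by the depth
# of their midpoint (DEJ -> surface), ties broken lateral -> mesial so that
# row ordering is deterministic when many rows share a depth.

#' Order rod profiles along a row
#'
#' Sorts by the x-axis coordinate of the centroid, ties broken by ascending
#' y.
#'
#' @param profiles Tibble with `centroid_x`, `centroid_y`.
#' @return The reordered tibble.
#' @export
order_profiles_by_x <- function(profiles) {
  if (nrow(profiles) == 0) abort("no profiles to order")
  arrange(profiles, .data$centroid_x, .data$centroid_y)
}

#' Assemble rod profiles of one tilt category into rows
#'
#' Links each profile to nearby same-category profiles within a gating
#' distance (`gate_factor` times the category's median nearest-neighbour
#' distance). Each profile joins its nearest gated neighbour, plus its
#' second-nearest when that link extends the chain on the opposite side
#' (direction consistency); connected components of the link graph are the
#' rows. Chains shorter than `min_chain` are kept as orphan rows flagged for
#' review, never dropped.
#'
#' @param profiles Tibble for a single tilt category with `centroid_x`,
#'   `centroid_y` (pixels) and a `tilt` column.
#' @param geometry An `enamel_map` (for the DEJ, used to order rows by
#'   depth).
#' @param gate_factor Gating multiple of the median nearest-neighbour
#'   distance.
#' @param min_chain Minimum members of a non-orphan row.
#' @return `profiles` with `row_id` (ordered by row midpoint depth, ties
#'   lateral to mesial), `seq_index` (order within row), and `row_orphan`.
#' @export
assemble_rows <- function(profiles, geometry, gate_factor = 2.5,
                          min_chain = 3L) {
  n <- nrow(profiles)
  if (n == 0) abort("no profiles to assemble")
  x <- profiles$centroid_x; y <- profiles$centroid_y
  if (n == 1) {
    comp <- 1L
  } else {
    nn <- .nn_dist(x, y)
    gate <- gate_factor * stats::median(nn)
    pairs <- .radius_pairs(x, y, gate)
    edges <- chain_links(x, y, pairs)
    comp <- .uf_components(n, edges)
  }
  out <- mutate(profiles, .comp = comp)
  # order rows by quantized midpoint depth, then by midpoint x
  mids <- out |>
    group_by(.data$.comp) |>
    summarise(mx = stats::median(.data$centroid_x),
              my = stats::median(.data$centroid_y),
              nmem = dplyr::n(), .groups = "drop")
  depth_px <- point_polyline_distance(mids$mx, mids$my, geometry$dej)
  bin_px <- 25 * geometry$scale
  mids$rank <- order(order(round(depth_px / bin_px), mids$mx))
  out <- out |>
    left_join(select(mids, ".comp", "rank", "nmem"), by = ".comp") |>
    mutate(row_id = .data$rank,
           row_orphan = .data$nmem < min_chain) |>
    select(-".comp", -"rank", -"nmem") |>
    arrange(.data$row_id) |>
    group_by(.data$row_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order_along_row(df), ]
      mutate(df, seq_index = row_number())
    }) |>
    ungroup()
  out
}

# Order row members along the row's principal axis (oriented towards
# increasing x, or increasing y for depth-running rows), ties broken by x
# then y. For rows running laterally this reduces to the classic sort by
# centroid x.
order_along_row <- function(df) {
  k <- nrow(df)
  if (k <= 1) return(seq_len(k))
  cx <- df$centroid_x - mean(df$centroid_x)
  cy <- df$centroid_y - mean(df$centroid_y)
  v <- eigen(crossprod(cbind(cx, cy)), symmetric = TRUE)$vectors[, 1]
  if (abs(v[1]) >= abs(v[2])) {
    if (v[1] < 0) v <- -v
  } else if (v[2] < 0) v <- -v
  order(cx * v[1] + cy * v[2], df$centroid_x, df$centroid_y)
}

# Direction-consistent chain links: keep each point's nearest gated
# neighbour, and its second-nearest when the two links open to opposite
# sides (angle between them > 90 degrees).
chain_links <- function(x, y, pairs) {
  if (nrow(pairs) == 0) return(matrix(integer(), 0, 2))
  i <- c(pairs[, 1], pairs[, 2])
  j <- c(pairs[, 2], pairs[, 1])
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  ord <- order(i, d)
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  rank <- stats::ave(seq_along(i), i, FUN = seq_along)
  first <- rank == 1
  keep <- first
  second <- rank == 2
  if (any(second)) {
    n1 <- j[first][match(i[second], i[first])]
    v1x <- x[n1] - x[i[second]]; v1y <- y[n1] - y[i[second]]
    v2x <- x[j[second]] - x[i[second]]; v2y <- y[j[second]] - y[i[second]]
    opposite <- (v1x * v2x + v1y * v2y) < 0
    keep[which(second)[opposite]] <- TRUE
  }
  cbind(i[keep], j[keep])
}

#' Summarise assembled rows
#'
#' Produces the per-row summary table: rods per row (RPR), the lateral and
#' mesial endpoints and the midpoint, the perpendicular distance of the
#' midpoint from the DEJ, row length as the sum of sequential inter-centroid
#' distances, means of the morphometric fields, and the circular mean angle.
#' For an even member count the midpoint is the mean of the two central
#' centroids.
#'
#' @param profiles Output of [assemble_rows()] (must carry `row_id`; members
#'   are re-ordered along each row's principal axis, which reduces to the
#'   classic sort by centroid x for laterally running rows).
#' @param geometry An `enamel_map`.
#' @param pixels_per_um Scale for the micrometre fields.
#' @return One row per rod row: tibble with `row_id`, `tilt`, `rpr`,
#'   endpoint/midpoint coordinates (pixels), `distance_from_dej_um`,
#'   `row_length_um`, `mean_area_um2`, `mean_feret_max_um`,
#'   `mean_feret_min_um`, circular-mean fields, `region`, `row_orphan`.
#' @export
summarize_rows <- function(profiles, geometry, pixels_per_um) {
  if (nrow(profiles) == 0) abort("empty row set")
  s <- pixels_per_um
  bb <- geometry$bbox
  one <- function(df) {
    df <- df[order_along_row(df), ]
    k <- nrow(df)
    mid <- if (k %% 2 == 1) {
      c(df$centroid_x[(k + 1) / 2], df$centroid_y[(k + 1) / 2])
    } else {
      c(mean(df$centroid_x[k / 2 + 0:1]), mean(df$centroid_y[k / 2 + 0:1]))
    }
    len <- if (k > 1) {
      sum(sqrt(diff(df$centroid_x)^2 + diff(df$centroid_y)^2))
    } else 0
    cm <- circular_mean(df$feret_angle_deg)
    tibble(
      tilt = df$tilt[1],
      rpr = k,
      lateral_x = df$centroid_x[1], lateral_y = df$centroid_y[1],
      mid_x = mid[1], mid_y = mid[2],
      mesial_x = df$centroid_x[k], mesial_y = df$centroid_y[k],
      distance_from_dej_um =
        point_polyline_distance(mid[1], mid[2], geometry$dej) / s,
      row_length_um = len / s,
      mean_area_um2 = mean(df$area_px2) / s^2,
      mean_feret_max_um = mean(df$feret_max_px) / s,
      mean_feret_min_um = mean(df$feret_min_px) / s,
      mean_deg = cm$mean_deg,
      circular_sd_deg = cm$circular_sd_deg,
      resultant_length = cm$resultant_length,
      region = assign_region(
        min(max((mid[1] - bb[["xmin"]]) / (bb[["xmax"]] - bb[["xmin"]]), 0), 1)),
      row_orphan = isTRUE(df$row_orphan[1])
    )
  }
  profiles |>
    group_by(.data$row_id) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup() |>
    arrange(.data$row_id)
}
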