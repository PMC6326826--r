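# Full analysis orchestration: category layers in, per-rod / per-row /
# regional tables out, with a deterministic manifest for reproducibility.

TILT_OF_CATEGORY <- c(inner_mesial = "mesial", inner_lateral = "lateral",
                      outer = NA, cej = NA)

#' Run the full rod-profile analysis pipeline
#'
#' Executes threshold -> particle extraction -> morphometry for each of the
#' four category layers, assembles inner-enamel rows, appends normalized
#' coordinates, regions, depth fractions and DEJ-relative angles, and
#' aggregates circular, decussation and spacing statistics.
#'
#' @param map An `enamel_map` with filled `layers` (from
#'   [simulate_enamel_map()], [render_color_maps()] or [read_enamel_map()]).
#' @param gate_factor,min_chain Row-assembly parameters (see
#'   [assemble_rows()]).
#' @param mouse_id,incisor_id,tooth_id Identifier coding carried into every
#'   output table.
#' @param dej_window_um Window for the local DEJ tangent fit.
#' @return A `rod_analysis` object: tibbles `rods`, `rows`, `pairs`,
#'   `regional`, a `summary` list and a reproducibility `manifest`. Access
#'   tables with [tidy()] and the one-row summary with [glance()].
#' @export
run_pipeline <- function(map, gate_factor = 2.5, min_chain = 3L,
                         mouse_id = 1L, incisor_id = "R", tooth_id = 1L,
                         dej_window_um = 50) {
  stopifnot(inherits(map, "enamel_map"))
  if (length(map$layers) == 0) abort("stage threshold: map has no layers")
  dims <- unique(lapply(map$layers, dim))
  if (length(dims) != 1) abort("stage threshold: layer dimensions differ")
  s <- map$scale
  log <- list()

  rods <- lapply(intersect(ROD_CATEGORIES, names(map$layers)), function(cat) {
    mask <- threshold_layer(map$layers[[cat]])
    labels <- extract_particles(mask)
    p <- measure_particles(labels)
    if (nrow(p) == 0) return(NULL)
    mutate(p, category = cat, tilt = TILT_OF_CATEGORY[[cat]])
  })
  rods <- list_rbind(rods)
  if (is.null(rods) || nrow(rods) == 0) {
    rods <- tibble(particle_id = integer(), area_px2 = numeric(),
                   centroid_x = numeric(), centroid_y = numeric(),
                   feret_max_px = numeric(), feret_min_px = numeric(),
                   feret_angle_deg = numeric(), category = character(),
                   tilt = character())
  }
  log$extracted <- nrow(rods)

  rods <- rods |>
    mutate(profile_id = dplyr::row_number(),
           mouse_id = mouse_id, incisor_id = incisor_id,
           tooth_id = tooth_id) |>
    to_micrometers(s)
  if (nrow(rods) > 0) {
    rods <- rods |>
      normalize_coords(map) |>
      mutate(region = assign_region(.data$norm_x)) |>
      depth_fraction(map) |>
      mutate(dej_relative_angle_deg = angle_relative_to_dej(
        .data$feret_angle_deg,
        dej_tangent_angle(.data$centroid_x, .data$centroid_y, map,
                          dej_window_um)))
  }

  # row assembly per tilt, then one joint depth-ordered numbering
  inner <- filter(rods, .data$category %in% c("inner_mesial", "inner_lateral"))
  if (nrow(inner) > 0) {
    assembled <- inner |>
      group_by(.data$tilt) |>
      dplyr::group_split() |>
      lapply(function(df) assemble_rows(df, map, gate_factor, min_chain)) |>
      list_rbind() |>
      rank_rows_jointly(map)
    rows_tbl <- summarize_rows(assembled, map, s)
    rods <- rods |>
      left_join(select(assembled, "profile_id", "row_id", "seq_index",
                       "row_orphan"),
                by = "profile_id")
  } else {
    rows_tbl <- tibble(row_id = integer(), tilt = character(),
                       rpr = integer(), mean_deg = numeric(),
                       region = integer(), row_orphan = logical())
    rods$row_id <- integer(0); rods$seq_index <- integer(0)
    rods$row_orphan <- logical(0)
  }
  log$rows <- nrow(rows_tbl)

  pairs <- decussation_by_rows(rows_tbl)
  spacing <- if (nrow(rods) > 0) spacing_summary(rods, s) else tibble()
  angles_regional <- if (nrow(rods) > 0) {
    rods |>
      group_by(.data$category, .data$tilt, .data$region) |>
      dplyr::reframe(circular_mean(.data$feret_angle_deg)) |>
      left_join(select(spacing, "category", "tilt", "region",
                       "spacing_mean_um", "spacing_sd_um"),
                by = c("category", "tilt", "region"))
  } else tibble()

  thickness <- measure_thickness(map)
  counts <- category_counts(rods, rows_tbl)
  grand <- function(tl) {
    a <- filter(rods, .data$tilt %in% tl)$feret_angle_deg
    if (length(a) == 0) NA_real_ else circular_mean(a)$mean_deg
  }
  summary <- list(
    n_total = nrow(rods),
    counts = counts,
    n_rows = nrow(rows_tbl),
    rows_per_tilt = attr(counts, "rows_per_tilt"),
    thickness = thickness,
    mesial_mean_deg = grand("mesial"),
    lateral_mean_deg = grand("lateral"),
    decussation_grand_deg =
      if (!is.na(grand("mesial")) && !is.na(grand("lateral"))) {
        decussation_from_means(grand("mesial"), grand("lateral"))
      } else NA_real_
  )
  log$pairs <- nrow(pairs)

  manifest <- list(
    package = "rodmap",
    version = as.character(utils::packageVersion("rodmap")),
    seed = map$config$seed %||% NA,
    scale_px_per_um = s,
    config = if (!is.null(map$config)) unclass(map$config) else NULL,
    input_digests = map$source_digests %||% list(),
    parameters = list(gate_factor = gate_factor, min_chain = min_chain,
                      dej_window_um = dej_window_um),
    stage_counts = log
  )

  structure(list(rods = rods, rows = rows_tbl, pairs = pairs,
                 regional = angles_regional, spacing = spacing,
                 summary = summary, manifest = manifest,
                 geometry = map[c("dej", "surface", "layer_boundary", "bbox",
                                  "scale", "thickness_um", "inner_um")]),
            class = "rod_analysis")
}

# joint numbering of rows over both tilts: quantized midpoint depth, then
# lateral -> mesial midpoint position
rank_rows_jointly <- function(assembled, map) {
  mids <- assembled |>
    group_by(.data$tilt, .data$row_id) |>
    summarise(mx = stats::median(.data$centroid_x),
              my = stats::median(.data$centroid_y), .groups = "drop")
  depth <- point_polyline_distance(mids$mx, mids$my, map$dej)
  bin <- 25 * map$scale
  mids$new_id <- order(order(round(depth / bin), mids$mx))
  assembled |>
    left_join(select(mids, "tilt", "row_id", "new_id"),
              by = c("tilt", "row_id")) |>
    mutate(row_id = .data$new_id) |>
    select(-"new_id")
}

#' @export
print.rod_analysis <- function(x, ...) {
  cat(sprintf(
    "<rod_analysis> %d rod profiles, %d rows, thickness %.1f um\n",
    x$summary$n_total, x$summary$n_rows, x$summary$thickness$total_um))
  print(x$summary$counts)
  invisible(x)
}

#' Tidy tables from a fitted rod analysis
#'
#' @param x A `rod_analysis`.
#' @param table One of `"rods"`, `"rows"`, `"pairs"`, `"regional"`,
#'   `"spacing"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.rod_analysis <- function(x, table = c("rods", "rows", "pairs",
                                           "regional", "spacing"), ...) {
  table <- match.arg(table)
  as_tibble(x[[table]])
}

#' One-row summary of a rod analysis
#'
#' The gross-organization summary: total and per-category counts with
#' percentages, row counts by tilt, enamel thickness split, tilt grand mean
#' directions and their decussation angle.
#'
#' @param x A `rod_analysis`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.rod_analysis <- function(x, ...) {
  cnt <- function(cat) {
    i <- match(cat, x$summary$counts$category)
    if (is.na(i)) 0L else x$summary$counts$n[i]
  }
  pct <- function(cat) {
    i <- match(cat, x$summary$counts$category)
    if (is.na(i)) 0 else x$summary$counts$percent[i]
  }
  rpt <- x$summary$rows_per_tilt
  nrt <- function(tl) {
    if (is.null(rpt)) return(NA_integer_)
    i <- match(tl, rpt$tilt)
    if (is.na(i)) 0L else rpt$n_rows[i]
  }
  tibble(
    n_total = x$summary$n_total,
    n_inner = cnt("inner_mesial") + cnt("inner_lateral"),
    n_inner_mesial = cnt("inner_mesial"),
    n_inner_lateral = cnt("inner_lateral"),
    n_outer = cnt("outer"),
    n_cej = cnt("cej"),
    pct_inner = pct("inner_mesial") + pct("inner_lateral"),
    pct_outer = pct("outer"),
    pct_cej = pct("cej"),
    n_rows = x$summary$n_rows,
    n_rows_mesial = nrt("mesial"),
    n_rows_lateral = nrt("lateral"),
    thickness_total_um = x$summary$thickness$total_um,
    thickness_inner_um = x$summary$thickness$inner_um,
    thickness_outer_um = x$summary$thickness$outer_um,
    mesial_mean_deg = x$summary$mesial_mean_deg,
    lateral_mean_deg = x$summary$lateral_mean_deg,
    decussation_grand_deg = x$summary$decussation_grand_deg
  )
}

#' Simulate-analyze-compare parameter recovery
#'
#' Generates a synthetic map from `config`, runs the full pipeline on the
#' rendered layers, and compares recovered quantities against the
#' generator's ground truth: per-category counts and row count (exact),
#' thickness (within one pixel), regional circular means of measured vs
#' true angles (tolerance in degrees), and within-row spacing against the
#' configured anchors (relative tolerance).
#'
#' @param config A [rod_config()].
#' @param seed Optional seed override.
#' @param angle_tol_deg,spacing_rel_tol,min_cell_n Tolerances and the
#'   minimum cell size for angle-cell comparisons.
#' @return Tibble: `parameter`, `truth`, `estimate`, `tolerance`, `pass`;
#'   the fitted `rod_analysis` is attached as attribute `analysis`.
#' @export
end_to_end_recovery <- function(config, seed = NULL, angle_tol_deg = 2,
                                spacing_rel_tol = 0.1, min_cell_n = 50) {
  map <- simulate_enamel_map(config, seed)
  truth <- map$truth
  an <- run_pipeline(map)
  g <- glance(an)
  s <- config$pixels_per_um

  rows <- list()
  add <- function(parameter, truth_v, est, tol) {
    tibble(parameter = parameter, truth = truth_v, estimate = est,
           tolerance = tol, pass = abs(est - truth_v) <= tol)
  }
  tcnt <- table(factor(truth$category, ROD_CATEGORIES))
  rows$total <- add("n_total", nrow(truth), g$n_total, 0)
  for (cat in ROD_CATEGORIES) {
    cnt_i <- match(cat, an$summary$counts$category)
    est <- if (is.na(cnt_i)) 0 else an$summary$counts$n[cnt_i]
    rows[[paste0("n_", cat)]] <- add(paste0("n_", cat),
                                     as.numeric(tcnt[[cat]]), est, 0)
  }
  rows$n_rows <- add("n_rows", length(unique(stats::na.omit(truth$true_row_id))),
                     g$n_rows, 0)
  rows$thickness <- add("thickness_um", config$thickness_um,
                        g$thickness_total_um, 1 / s)

  # regional circular means: measured vs true angles
  angdiff <- function(a, b) {
    d <- abs(a - b) %% 360; ifelse(d > 180, 360 - d, d)
  }
  cells <- truth |>
    filter(!is.na(.data$tilt)) |>
    group_by(.data$tilt, .data$region) |>
    summarise(n = dplyr::n(),
              true_mean = circular_mean(.data$true_angle_deg)$mean_deg,
              .groups = "drop") |>
    filter(n >= min_cell_n)
  for (i in seq_len(nrow(cells))) {
    est_ang <- an$rods |>
      filter(.data$tilt %in% cells$tilt[i], .data$region == cells$region[i])
    est <- circular_mean(est_ang$feret_angle_deg)$mean_deg
    nm <- sprintf("angle_%s_r%d_deg", cells$tilt[i], cells$region[i])
    d <- angdiff(est, cells$true_mean[i])
    rows[[nm]] <- tibble(parameter = nm, truth = cells$true_mean[i],
                         estimate = est, tolerance = angle_tol_deg,
                         pass = d <= angle_tol_deg)
  }

  # spacing: recovered within-row means vs configured anchors
  for (tl in c("mesial", "lateral")) {
    anchors <- config$spacing_field[[paste0("inner_", tl)]]
    sp <- filter(an$spacing, .data$tilt %in% tl)
    for (r in intersect(1:4, sp$region)) {
      est <- sp$spacing_mean_um[sp$region == r]
      nm <- sprintf("spacing_%s_r%d_um", tl, r)
      rows[[nm]] <- add(nm, anchors[r], est, spacing_rel_tol * anchors[r])
    }
  }
  out <- list_rbind(rows)
  attr(out, "analysis") <- an
  out
}
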