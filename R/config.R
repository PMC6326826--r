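#' Configuration for the synthetic enamel-map generator
#'
#' Builds a validated configuration describing one synthetic incisor
#' cross-section: the enamel band geometry, how many rod profiles of each
#' category to place, the regional tilt-angle field, the regional spacing
#' field, and the rendered shape of each rod category.
#'
#' Defaults describe a 7-week-old mouse mandibular incisor cross-section:
#' a 121 micrometre thick band (inner layer 100, outer 21) carrying 7233 rod
#' profiles split 70/27/3 percent between the inner layer, the outer layer
#' and the cementoenamel junctions, with the inner profiles organised into
#' 124 rows of alternating mesial/lateral tilt. Angle anchors are circular
#' means (degrees, counterclockwise from 3 o'clock) per region 1 (lateral)
#' to 4 (mesial); spacing anchors are mean inter-centroid distances in
#' micrometres.
#'
#' @param seed Integer seed; one seed reproduces a map bit-exactly.
#' @param pixels_per_um Raster scale (pixels per micrometre).
#' @param total_profiles Total rod profiles to place.
#' @param category_fractions Named fractions for inner/outer/cej; must sum
#'   to 1.
#' @param n_rows Even number of inner-enamel rows (half mesial, half lateral
#'   tilt).
#' @param thickness_um,inner_um Total and inner-layer enamel thickness
#'   (micrometres); the outer-layer thickness is the difference.
#' @param curvature_radius_um Dentoenamel-junction arc radius in
#'   micrometres, or `"flat"` for a straight band.
#' @param band_width_um Band length from lateral to mesial terminus
#'   (micrometres).
#' @param angle_frame `"section"` anchors the angle field in the plane of
#'   section; `"dej"` anchors it in the local DEJ-parallel frame (only
#'   different on curved bands).
#' @param angle_field Per-category list of `mean` and `sd` vectors (length
#'   4, degrees), regions lateral (1) to mesial (4).
#' @param spacing_field Per-category length-4 vectors of mean inter-centroid
#'   spacing (micrometres).
#' @param transition_halfwidth Half-width (normalized x) of the linear ramp
#'   joining regional plateaus of the angle/spacing fields.
#' @param shapes Rendered shape parameters (micrometres): ellipse axes for
#'   inner rods, rhombus diagonals for outer rods, axis ranges and
#'   superellipse exponent range for CEJ blobs.
#' @param clearance_px Minimum rendered gap between any two profiles.
#' @param cej_mesial_fraction Fraction of CEJ profiles placed at the mesial
#'   terminus.
#' @param jitter List: `spacing` (relative jitter of within-row gaps),
#'   `lateral_um` (centroid jitter across the row axis), `start_um` (row
#'   start-depth jitter).
#' @param edge_margin_um Blank margin around the band in the raster.
#' @param lane_margin_um Band-end zone reserved for CEJ profiles (no rows).
#'
#' @return A list with class `rod_config`.
#' @export
#' @examples
#' cfg <- rod_config(total_profiles = 400, n_rows = 12, band_width_um = 112)
#' cfg$outer_um
rod_config <- function(seed = 1L,
                       pixels_per_um = 16,
                       total_profiles = 7233L,
                       category_fractions = c(inner = 0.70, outer = 0.27,
                                              cej = 0.03),
                       n_rows = 124L,
                       thickness_um = 121,
                       inner_um = 100,
                       curvature_radius_um = "flat",
                       band_width_um = 744,
                       angle_frame = c("section", "dej"),
                       angle_field = NULL,
                       spacing_field = NULL,
                       transition_halfwidth = 0.025,
                       shapes = NULL,
                       clearance_px = 2,
                       cej_mesial_fraction = 5 / 6,
                       jitter = NULL,
                       edge_margin_um = 4,
                       lane_margin_um = 20) {
  angle_frame <- match.arg(angle_frame)
  angle_field <- modify_defaults(default_angle_field(), angle_field)
  spacing_field <- modify_defaults(default_spacing_field(), spacing_field)
  shapes <- modify_defaults(default_shapes(), shapes)
  jitter <- modify_defaults(list(spacing = 0.02, lateral_um = 0.25,
                                 start_um = 0.3), jitter)

  if (pixels_per_um <= 0) abort("pixels_per_um must be positive")
  if (total_profiles <= 0) abort("total_profiles must be positive")
  if (thickness_um <= 0 || inner_um <= 0 || inner_um >= thickness_um) {
    abort("need 0 < inner_um < thickness_um")
  }
  if (abs(sum(category_fractions) - 1) > 1e-9) {
    abort("category_fractions must sum to 1")
  }
  if (n_rows <= 0 || n_rows %% 2 != 0) abort("n_rows must be even and positive")
  if (!identical(curvature_radius_um, "flat")) {
    if (!is.numeric(curvature_radius_um) ||
        curvature_radius_um <= thickness_um) {
      abort("curvature radius must exceed the band thickness, or be \"flat\"")
    }
  }
  for (cat in names(angle_field)) {
    f <- angle_field[[cat]]
    if (any(f$sd <= 0)) abort("all angle-field SDs must be positive")
    if (any(f$mean < 0 | f$mean >= 180)) {
      abort("angle-field means must lie in [0, 180)")
    }
  }
  if (any(unlist(spacing_field) <= 0)) abort("spacing must be positive")

  structure(list(
    seed = as.integer(seed),
    pixels_per_um = pixels_per_um,
    total_profiles = as.integer(total_profiles),
    category_fractions = category_fractions,
    n_rows = as.integer(n_rows),
    thickness_um = thickness_um,
    inner_um = inner_um,
    outer_um = thickness_um - inner_um,
    curvature_radius_um = curvature_radius_um,
    band_width_um = band_width_um,
    angle_frame = angle_frame,
    angle_field = angle_field,
    spacing_field = spacing_field,
    transition_halfwidth = transition_halfwidth,
    shapes = shapes,
    clearance_px = clearance_px,
    cej_mesial_fraction = cej_mesial_fraction,
    jitter = jitter,
    edge_margin_um = edge_margin_um,
    lane_margin_um = lane_margin_um
  ), class = "rod_config")
}

default_angle_field <- function() {
  list(
    inner_mesial = list(mean = c(58.4, 88.0, 118.0, 147.0),
                        sd = c(12.5, 13.0, 13.6, 14.1)),
    inner_lateral = list(mean = c(29.9, 45.0, 60.0, 75.6),
                         sd = c(52.8, 35.0, 22.0, 13.5)),
    outer = list(mean = c(27.0, 50.0, 80.0, 115.0),
                 sd = c(55.0, 40.0, 28.0, 24.0)),
    cej = list(mean = c(101.0, 101.0, 101.0, 101.0),
               sd = c(43.9, 43.9, 43.9, 43.9))
  )
}

default_spacing_field <- function() {
  list(
    inner_mesial = c(2.3, 2.2, 2.1, 2.0),
    inner_lateral = c(2.3, 2.15, 2.15, 4.3),
    outer = c(2.1, 1.9, 1.6, 1.9),
    cej = c(2.1, 2.1, 2.1, 2.1)
  )
}

default_shapes <- function() {
  list(
    ellipse_axes_um = c(long = 1.8, short = 0.6),
    rhombus_diag_um = c(long = 1.3, short = 0.65),
    cej_axes_um = list(long = c(1.0, 1.3), short = c(0.6, 0.9)),
    cej_exponent = c(1.6, 3.0)
  )
}

# shallow-merge user values over defaults (one level of nesting)
modify_defaults <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

#' Integer rod counts per category implied by a configuration
#'
#' Apportions `total_profiles` over the inner/outer/CEJ fractions by the
#' largest-remainder rule, so the counts always sum to the configured total.
#'
#' @param config A [rod_config()].
#' @return Named integer vector (`inner`, `outer`, `cej`).
#' @export
#' @examples
#' category_targets(rod_config())
category_targets <- function(config) {
  stopifnot(inherits(config, "rod_config"))
  n <- largest_remainder(config$total_profiles, config$category_fractions)
  setNames(n, names(config$category_fractions))
}

#' @export
print.rod_config <- function(x, ...) {
  curv <- if (identical(x$curvature_radius_um, "flat")) "flat" else {
    sprintf("arc, r = %g um", x$curvature_radius_um)
  }
  cat(sprintf(
    paste0("<rod_config> %d profiles (%s), %d rows, band %g x %g um (%s), ",
           "%g px/um, seed %d\n"),
    x$total_profiles,
    paste(category_targets(x), collapse = "/"),
    x$n_rows, x$band_width_um, x$thickness_um, curv, x$pixels_per_um, x$seed))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The file mirrors the field names of [rod_config()]; unspecified fields
#' keep their defaults on reading.
#'
#' @param config A [rod_config()].
#' @param path File path.
#' @return `read_rod_config()` returns a `rod_config`;
#'   `write_rod_config()` returns `path` invisibly.
#' @export
write_rod_config <- function(config, path) {
  stopifnot(inherits(config, "rod_config"))
  x <- unclass(config)
  x$outer_um <- NULL # derived
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_rod_config
#' @export
read_rod_config <- function(path) {
  x <- yaml::read_yaml(path)
  x <- x[setdiff(names(x), "outer_um")]
  if (!is.null(x$category_fractions)) {
    x$category_fractions <- unlist(x$category_fractions)
  }
  if (!is.null(x$shapes)) {
    for (nm in c("ellipse_axes_um", "rhombus_diag_um")) {
      if (!is.null(x$shapes[[nm]])) x$shapes[[nm]] <- unlist(x$shapes[[nm]])
    }
  }
  do.call(rod_config, x)
}
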