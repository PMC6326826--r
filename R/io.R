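# Readers and writers: PNG category layers, CSV geometry/ground-truth
# tables, YAML configuration and the deterministic analysis outputs.

LAYER_COLORS <- list(inner_mesial = c(0, 0, 0), inner_lateral = c(1, 0, 0),
                     outer = c(0, 0, 1), cej = c(1, 0, 1))

#' Write a synthetic enamel map to disk
#'
#' One grayscale PNG per category layer (rods dark on white), a composite
#' RGB preview using the standard color coding (inner-mesial black,
#' inner-lateral red, outer blue, CEJ magenta), polyline tables and map
#' metadata as CSV/YAML, plus ground truth and configuration when present.
#'
#' @param map An `enamel_map`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_enamel_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cat in names(map$layers)) {
    png::writePNG(1 - map$layers[[cat]] * 1,
                  file.path(dir, paste0(cat, ".png")))
  }
  if (length(map$layers) == 4) {
    comp <- array(1, dim = c(map$height_px, map$width_px, 3))
    for (cat in names(map$layers)) {
      idx <- which(map$layers[[cat]])
      for (ch in 1:3) {
        plane <- comp[, , ch]
        plane[idx] <- LAYER_COLORS[[cat]][ch]
        comp[, , ch] <- plane
      }
    }
    png::writePNG(comp, file.path(dir, "composite.png"))
  }
  geom <- bind_rows(
    mutate(map$dej, polyline = "dej"),
    mutate(map$surface, polyline = "surface"),
    mutate(map$layer_boundary, polyline = "layer_boundary"))
  readr::write_csv(select(geom, "polyline", "u", "x", "y"),
                   file.path(dir, "geometry.csv"))
  meta <- list(
    width_px = map$width_px, height_px = map$height_px, scale = map$scale,
    thickness_um = map$thickness_um, inner_um = map$inner_um,
    bbox = as.list(map$bbox),
    cej_lateral = as.list(map$cej_lateral),
    cej_mesial = as.list(map$cej_mesial),
    frame = map$frame)
  yaml::write_yaml(meta, file.path(dir, "map.yml"))
  if (!is.null(map$truth)) {
    readr::write_csv(map$truth, file.path(dir, "truth.csv"))
  }
  if (!is.null(map$config)) {
    write_rod_config(map$config, file.path(dir, "config.yml"))
  }
  invisible(dir)
}

#' Read an enamel map from disk
#'
#' Rebuilds the `enamel_map` written by [write_enamel_map()] (or assembled
#' by hand in the same format: four category PNGs, `geometry.csv`,
#' `map.yml`). Input file digests are recorded for the run manifest.
#'
#' @param dir Directory containing the map files.
#' @return An `enamel_map`.
#' @export
read_enamel_map <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "map.yml"))
  geom <- readr::read_csv(file.path(dir, "geometry.csv"),
                          show_col_types = FALSE)
  layers <- list()
  files <- character()
  for (cat in ROD_CATEGORIES) {
    f <- file.path(dir, paste0(cat, ".png"))
    if (file.exists(f)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      layers[[cat]] <- img < 0.5
      files <- c(files, f)
    }
  }
  cfgf <- file.path(dir, "config.yml")
  config <- if (file.exists(cfgf)) read_rod_config(cfgf) else NULL
  truthf <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthf)) {
    readr::read_csv(truthf, show_col_types = FALSE)
  } else NULL
  pick <- function(nm) filter(geom, .data$polyline == nm) |>
    select("u", "x", "y")
  structure(list(
    width_px = meta$width_px, height_px = meta$height_px,
    scale = meta$scale,
    frame = meta$frame,
    dej = pick("dej"), surface = pick("surface"),
    layer_boundary = pick("layer_boundary"),
    cej_lateral = unlist(meta$cej_lateral),
    cej_mesial = unlist(meta$cej_mesial),
    bbox = unlist(meta$bbox),
    inner_um = meta$inner_um, thickness_um = meta$thickness_um,
    layers = layers, config = config, truth = truth,
    source_digests = as.list(tools::md5sum(
      c(files, file.path(dir, c("geometry.csv", "map.yml")))))
  ), class = "enamel_map")
}

#' Write analysis tables and the run manifest
#'
#' Writes `rods.csv`, `rows.csv`, `pairs.csv`, `regional.csv`,
#' `spacing.csv`, `summary.csv` and `manifest.yml`. All outputs are
#' deterministic: re-running an identical configuration and seed reproduces
#' them byte for byte.
#'
#' @param analysis A `rod_analysis`.
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "rod_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    rods = file.path(dir, "rods.csv"),
    rows = file.path(dir, "rows.csv"),
    pairs = file.path(dir, "pairs.csv"),
    regional = file.path(dir, "regional.csv"),
    spacing = file.path(dir, "spacing.csv"),
    summary = file.path(dir, "summary.csv")
  )
  readr::write_csv(analysis$rods, paths[["rods"]])
  readr::write_csv(analysis$rows, paths[["rows"]])
  readr::write_csv(analysis$pairs, paths[["pairs"]])
  readr::write_csv(analysis$regional, paths[["regional"]])
  readr::write_csv(analysis$spacing, paths[["spacing"]])
  readr::write_csv(glance(analysis), paths[["summary"]])
  manifest <- analysis$manifest
  manifest$outputs <- setNames(as.list(unname(tools::md5sum(unname(paths)))),
                               names(paths))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(c(paths, manifest = file.path(dir, "manifest.yml")))
}

#' Retrieve the run manifest of an analysis
#'
#' @param analysis A `rod_analysis`.
#' @return The manifest list (config snapshot, seed, parameters, stage
#'   record counts, input digests).
#' @export
run_manifest <- function(analysis) {
  stopifnot(inherits(analysis, "rod_analysis"))
  analysis$manifest
}
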