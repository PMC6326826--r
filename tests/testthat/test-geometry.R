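test_that("flat band geometry gives parallel polylines at the right depth", {
  cfg <- rod_config(pixels_per_um = 1, band_width_um = 100)
  g <- build_band_geometry(cfg)
  expect_true(all(abs(g$surface$y - g$dej$y - 121) < 1e-9))
  expect_true(all(abs(g$layer_boundary$y - g$dej$y - 100) < 1e-9))
  expect_error(build_band_geometry(rod_config(pixels_per_um = 0)))
})

test_that("arc band keeps DEJ-to-surface normal distance at the thickness", {
  cfg <- rod_config(curvature_radius_um = 1000, band_width_um = 300)
  g <- build_band_geometry(cfg)
  # sample 100 surface points, measure numerically to the DEJ
  idx <- round(seq(3, nrow(g$surface) - 2, length.out = 100))
  d <- rodmap:::point_polyline_distance(g$surface$x[idx], g$surface$y[idx],
                                        g$dej)
  expect_true(all(abs(d - 121 * cfg$pixels_per_um) <= 1))
})

test_that("layer boundary sits at depth fraction 100/121 = 0.826", {
  g <- build_band_geometry(rod_config(band_width_um = 200))
  pts <- tibble::tibble(centroid_x = g$layer_boundary$x[5:20],
                        centroid_y = g$layer_boundary$y[5:20])
  f <- depth_fraction(pts, g)$depth_fraction
  expect_true(all(abs(f - 0.826) < 0.005))
})

test_that("normalization is an exact involution and hits the box corners", {
  g <- build_band_geometry(small_config())
  bb <- g$bbox
  corners <- tibble::tibble(centroid_x = bb[c("xmin", "xmax")],
                            centroid_y = bb[c("ymin", "ymax")])
  n <- normalize_coords(corners, g)
  expect_equal(n$norm_x, c(0, 1))
  expect_equal(n$norm_y, c(0, 1))
  set.seed(1)
  pts <- tibble::tibble(
    centroid_x = runif(50, bb["xmin"], bb["xmax"]),
    centroid_y = runif(50, bb["ymin"], bb["ymax"]))
  n <- normalize_coords(pts, g)
  back_x <- bb[["xmin"]] + n$norm_x * (bb[["xmax"]] - bb[["xmin"]])
  back_y <- bb[["ymin"]] + n$norm_y * (bb[["ymax"]] - bb[["ymin"]])
  expect_true(max(abs(back_x - pts$centroid_x),
                  abs(back_y - pts$centroid_y)) < 1e-9)
})

test_that("region bins are half-open with the right edge closed", {
  expect_identical(assign_region(c(0, 0.26, 0.5, 1)), c(1L, 2L, 3L, 4L))
  expect_identical(assign_region(0.25), 2L)
  expect_error(assign_region(1.2), "range")
  expect_error(assign_region(-0.1), "range")
  # region assignment partitions uniform profiles near-evenly
  set.seed(2)
  r <- assign_region(runif(20000))
  expect_identical(length(r), 20000L)
  expect_true(all(abs(table(r) / 20000 - 0.25) < 0.25 * 0.03))
})

test_that("thickness is measured at the point of maximum convexity", {
  flat <- measure_thickness(build_band_geometry(rod_config()))
  expect_equal(flat$total_um, 121, tolerance = 1e-6)
  expect_equal(flat$inner_um, 100, tolerance = 1e-6)
  expect_equal(flat$outer_um, 21, tolerance = 1e-6)
  # explicit unit conversion: 2 px/um band is still 121 um
  two <- measure_thickness(build_band_geometry(
    rod_config(pixels_per_um = 2, band_width_um = 200)))
  expect_equal(two$total_um, 121, tolerance = 1 / 2)
  # curvature does not change the measurement (within 1 px)
  for (R in c(600, 2000)) {
    arc <- measure_thickness(build_band_geometry(
      rod_config(curvature_radius_um = R, band_width_um = 300)))
    expect_equal(arc$total_um, 121, tolerance = 1 / 16)
    expect_equal(arc$inner_um, 100, tolerance = 1 / 16)
  }
  # translation of the band (larger margin) leaves thickness unchanged
  sh <- measure_thickness(build_band_geometry(
    rod_config(edge_margin_um = 37, band_width_um = 200)))
  expect_equal(sh$total_um, 121, tolerance = 1e-6)
})

test_that("depth fraction is 0 at the DEJ, 1 at the surface, errors outside", {
  g <- build_band_geometry(rod_config(band_width_um = 200))
  mids <- 10:12
  pts <- tibble::tibble(
    profile_id = 1:6,
    centroid_x = c(g$dej$x[mids], g$surface$x[mids]),
    centroid_y = c(g$dej$y[mids], g$surface$y[mids]))
  f <- depth_fraction(pts, g)$depth_fraction
  expect_equal(f, c(0, 0, 0, 1, 1, 1), tolerance = 1e-6)
  out <- tibble::tibble(profile_id = 99, centroid_x = g$dej$x[10],
                        centroid_y = g$dej$y[10] - 100)
  expect_error(depth_fraction(out, g), "99")
})

test_that("DEJ-relative angles flatten regional gradients on curved bands", {
  expect_equal(angle_relative_to_dej(50, 0), 50)
  expect_equal(angle_relative_to_dej(10, 30), 160)
  # constant DEJ-frame field on an arc: section-frame angles vary along the
  # band, DEJ-relative angles do not
  cfg <- rod_config(
    curvature_radius_um = 400, band_width_um = 300, total_profiles = 500,
    n_rows = 16, angle_frame = "dej",
    angle_field = list(
      inner_mesial = list(mean = rep(104, 4), sd = rep(1, 4)),
      inner_lateral = list(mean = rep(48.6, 4), sd = rep(1, 4))))
  map <- simulate_enamel_map(cfg, seed = 3)
  an <- run_pipeline(map)
  r <- dplyr::filter(an$rods, tilt == "mesial")
  expect_gt(sd(r$feret_angle_deg), 2 * sd(r$dej_relative_angle_deg))
})
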