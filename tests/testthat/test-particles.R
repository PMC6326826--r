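test_that("thresholding matches rendered foreground and is idempotent", {
  expect_error(threshold_layer(matrix(numeric(0), 0, 0)), "empty")
  blank <- matrix(1, 10, 10)
  expect_equal(sum(threshold_layer(blank)), 0)
  m <- raster_ellipse(40, 40, 20, 20, 8, 3, 30)
  img <- 1 - m * 1 # dark ellipse on white
  expect_equal(sum(threshold_layer(img)), sum(m))
  expect_identical(threshold_layer(m), m) # binary input is a fixed point
  # synthetic layer: foreground pixel count equals rendered pixel count
  map <- simulate_enamel_map(small_config(total_profiles = 60, n_rows = 4),
                             seed = 2)
  lay <- map$layers$inner_mesial
  expect_equal(sum(threshold_layer(1 - lay * 1)), sum(lay))
})

test_that("particle labeling is 8-connected with contiguous labels", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE; m[7:8, 7:8] <- TRUE
  expect_identical(attr(extract_particles(m), "n"), 2L)
  # touching only at one corner: a single particle under 8-connectivity
  d <- matrix(FALSE, 10, 10)
  d[2:3, 2:3] <- TRUE; d[4:5, 4:5] <- TRUE
  expect_identical(attr(extract_particles(d), "n"), 1L)
  expect_identical(attr(extract_particles(matrix(FALSE, 5, 5)), "n"), 0L)
  lab <- extract_particles(m)
  expect_setequal(unique(lab[lab > 0]), 1:2)
})

test_that("square and single-pixel Feret geometry follow the conventions", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  p <- measure_particles(extract_particles(m))
  expect_equal(p$feret_max_px, sqrt(200), tolerance = 1e-9)
  expect_equal(p$feret_min_px, 10, tolerance = 1e-9)
  expect_equal(p$feret_angle_deg, 45) # tie broken to the smaller angle
  expect_equal(p$area_px2, 100)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  q <- measure_particles(extract_particles(one))
  expect_equal(q$feret_max_px, sqrt(2), tolerance = 1e-9)
  expect_equal(q$feret_min_px, 1, tolerance = 1e-9)
  expect_error(measure_particles(extract_particles(one), ids = 5),
               "unknown")
})

test_that("a long rendered ellipse recovers its orientation and length", {
  m <- raster_ellipse(120, 120, 60.3, 60.7, 20, 5, 147)
  p <- measure_particles(extract_particles(m))
  expect_lt(ang_diff(p$feret_angle_deg, 147), 2)
  expect_lt(abs(p$feret_max_px - 40), 2)
  expect_equal(p$centroid_x, 60.3, tolerance = 0.5)
  expect_equal(p$centroid_y, 60.7, tolerance = 0.5)
})

test_that("Feret widths equal the exhaustive-rotation oracle on random blobs", {
  set.seed(11)
  for (k in 1:30) {
    b <- random_blob(sample(10:40, 1))
    m <- matrix(FALSE, 100, 100)
    m[cbind(101 - b[, "y"], b[, "x"])] <- TRUE # world -> raster rows
    lab <- extract_particles(m)
    # the blob may split into several 8-connected pieces; test each
    p <- measure_particles(lab)
    H <- nrow(m)
    fg <- which(lab > 0)
    rows <- ((fg - 1) %% H) + 1; cols <- ((fg - 1) %/% H) + 1
    for (i in p$particle_id) {
      sel <- lab[fg] == i
      o <- feret_brute(cols[sel] - 0.5, H - rows[sel] + 0.5)
      expect_lt(abs(p$feret_max_px[p$particle_id == i] - o["max"]), 0.05)
      expect_lt(abs(p$feret_min_px[p$particle_id == i] - o["min"]), 0.05)
    }
  }
})

test_that("Feret invariants: ordering, area conservation, 90-degree rotation", {
  set.seed(12)
  m <- matrix(FALSE, 160, 160)
  for (k in 1:6) {
    b <- random_blob(25)
    m[cbind(161 - b[, "y"] - (k %% 3) * 25, b[, "x"] + (k %% 2) * 60)] <- TRUE
  }
  lab <- extract_particles(m)
  p <- measure_particles(lab)
  expect_true(all(p$feret_max_px >= p$feret_min_px))
  expect_true(all(p$feret_min_px > 0))
  expect_equal(sum(p$area_px2), sum(m))
  # rotate the raster 90 degrees: angles shift by 90 (mod 180)
  m90 <- t(m)[ncol(m):1, ]
  p90 <- measure_particles(extract_particles(m90))
  a_rot <- (p90$feret_angle_deg + 90) %% 180
  # every original orientation appears among the rotated ones (axial
  # distance under 1 degree)
  for (a in p$feret_angle_deg) {
    d <- abs(a - a_rot)
    expect_lt(min(pmin(d, 180 - d)), 1)
  }
})

test_that("micrometre conversion scales lengths and areas", {
  p <- tibble::tibble(area_px2 = 400, feret_max_px = 100, feret_min_px = 40,
                      centroid_x = 10, centroid_y = 20)
  q <- to_micrometers(p, 2)
  expect_equal(q$feret_max_um, 50)
  expect_equal(q$area_um2, 100)
  expect_equal(q$centroid_x_um, 5)
  id <- to_micrometers(p, 1)
  expect_equal(id$feret_max_um, p$feret_max_px)
  expect_error(to_micrometers(p, 0), "positive")
})
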