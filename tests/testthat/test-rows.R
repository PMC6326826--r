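test_that("profiles sort by centroid x with y as tiebreak", {
  p <- tibble::tibble(centroid_x = c(5, 1, 3), centroid_y = c(1, 1, 1))
  expect_equal(order_profiles_by_x(p)$centroid_x, c(1, 3, 5))
  tie <- tibble::tibble(centroid_x = c(2, 2), centroid_y = c(2, 1))
  expect_equal(order_profiles_by_x(tie)$centroid_y, c(1, 2))
  expect_error(order_profiles_by_x(p[0, ]))
})

test_that("inter-centroid distance is the Euclidean formula", {
  expect_equal(inter_centroid_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(inter_centroid_distance(c(2, 7), c(2, 7)), 0)
  set.seed(41)
  a <- matrix(runif(200, -50, 50), ncol = 2)
  b <- matrix(runif(200, -50, 50), ncol = 2)
  d <- inter_centroid_distance(a, b)
  oracle <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  expect_equal(d, oracle)
  expect_equal(d, inter_centroid_distance(b, a)) # symmetry
})

test_that("two separated chains assemble into two rows of ten", {
  geom <- build_band_geometry(small_config())
  p <- tibble::tibble(
    centroid_x = c(400 + (1:10) * 2, 700 + (1:10) * 2),
    centroid_y = rep(c(500, 520), each = 10) + c(1:10, 1:10) * 30,
    tilt = "mesial")
  rows <- assemble_rows(p, geom)
  expect_equal(length(unique(rows$row_id)), 2)
  expect_equal(unname(table(rows$row_id)), c(10L, 10L), ignore_attr = TRUE)
  expect_true(all(!rows$row_orphan))
})

test_that("a lone profile becomes a flagged orphan row", {
  geom <- build_band_geometry(small_config())
  p <- tibble::tibble(centroid_x = 500, centroid_y = 600, tilt = "mesial")
  rows <- assemble_rows(p, geom)
  expect_equal(rows$row_id, 1L)
  expect_true(rows$row_orphan)
  s <- summarize_rows(dplyr::mutate(rows, area_px2 = 10, feret_max_px = 4,
                                    feret_min_px = 2, feret_angle_deg = 90),
                      geom, 16)
  expect_equal(s$rpr, 1L)
  expect_equal(s$row_length_um, 0)
  expect_equal(s$mid_x, s$lateral_x)
  expect_equal(s$mid_x, s$mesial_x)
})

test_that("row summaries follow the defined midpoint and length rules", {
  geom <- build_band_geometry(small_config())
  base <- tibble::tibble(
    centroid_x = 500 + 16 * (0:2), centroid_y = 800,
    tilt = "lateral", row_id = 1L, row_orphan = FALSE,
    area_px2 = 100, feret_max_px = 20, feret_min_px = 8,
    feret_angle_deg = c(40, 50, 60))
  s <- summarize_rows(base, geom, 16)
  expect_equal(s$rpr, 3L)
  expect_equal(s$row_length_um, 2) # 2 unit gaps at 1 um each
  expect_equal(s$mid_x, 516) # odd count: the middle member
  expect_equal(s$mean_deg, circ_mean_oracle(c(40, 50, 60)),
               tolerance = 1e-9)
  even <- dplyr::bind_rows(base, dplyr::mutate(base[3, ],
                                               centroid_x = 548))
  s2 <- summarize_rows(even, geom, 16)
  expect_equal(s2$mid_x, (516 + 532) / 2) # even count: mean of central two
  # row length is at least the endpoint separation
  expect_gte(s2$row_length_um,
             (s2$mesial_x - s2$lateral_x) / 16 - 1e-9)
  expect_error(summarize_rows(base[0, ], geom, 16))
})

test_that("row length is invariant to translating the map", {
  geom <- build_band_geometry(small_config())
  set.seed(42)
  p <- tibble::tibble(
    centroid_x = 500 + cumsum(runif(8, 20, 40)),
    centroid_y = 700 + cumsum(runif(8, -10, 10)),
    tilt = "mesial", row_id = 1L, row_orphan = FALSE,
    area_px2 = 10, feret_max_px = 5, feret_min_px = 2,
    feret_angle_deg = runif(8, 80, 120))
  s1 <- summarize_rows(p, geom, 16)
  p2 <- dplyr::mutate(p, centroid_x = centroid_x + 57,
                      centroid_y = centroid_y - 23)
  s2 <- summarize_rows(p2, geom, 16)
  expect_equal(s1$row_length_um, s2$row_length_um, tolerance = 1e-9)
})

test_that("assembly recovers generated rows and their member order", {
  cfg <- small_config(seed = 43)
  map <- simulate_enamel_map(cfg)
  an <- run_pipeline(map)
  inner <- dplyr::filter(an$rods, !is.na(row_id))
  tr <- dplyr::filter(map$truth, !is.na(true_row_id))
  idx <- match_to_truth(inner$centroid_x, inner$centroid_y,
                        tr$true_x_px, tr$true_y_px)
  expect_false(anyNA(idx))
  # partition matches ground truth almost perfectly
  ari <- mclust::adjustedRandIndex(inner$row_id, tr$true_row_id[idx])
  expect_gte(ari, 0.99)
  # exhaustive and exclusive: every inner profile in exactly one row
  expect_equal(sum(an$rows$rpr), nrow(inner))
  expect_equal(nrow(an$rows), cfg$n_rows)
  expect_equal(sum(an$rows$tilt == "mesial"), cfg$n_rows / 2)
  # within-row ordering matches the generated sequence (principal-axis
  # ordering follows the chain, up to a global flip per row)
  one_row <- inner[inner$row_id == an$rows$row_id[3], ]
  true_seq <- tr$true_seq_index[idx[inner$row_id == an$rows$row_id[3]]]
  ord <- order(one_row$seq_index)
  expect_true(all(diff(true_seq[ord]) == 1) ||
                all(diff(true_seq[ord]) == -1))
})

test_that("configured spacing drives row length", {
  # 20 members at 4 um spacing: row length within 5% of 76 um
  cfg <- rod_config(
    total_profiles = 80, n_rows = 4, band_width_um = 120,
    category_fractions = c(inner = 1, outer = 0, cej = 0),
    spacing_field = list(inner_mesial = rep(4, 4),
                         inner_lateral = rep(4, 4),
                         outer = rep(2, 4), cej = rep(2, 4)),
    seed = 44)
  map <- simulate_enamel_map(cfg)
  an <- run_pipeline(map)
  expect_equal(an$rows$rpr, rep(20L, 4))
  expect_true(all(abs(an$rows$row_length_um - 76) / 76 < 0.05))
})
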