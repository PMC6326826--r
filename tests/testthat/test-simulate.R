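test_that("layout respects counts, rows and alternation", {
  cfg <- small_config(seed = 31)
  geom <- build_band_geometry(cfg)
  rec <- sample_rod_layout(cfg, geom)
  expect_equal(nrow(rec), cfg$total_profiles)
  targets <- category_targets(cfg)
  cnt <- table(factor(rec$category, CATS))
  expect_equal(unname(cnt[["inner_mesial"]] + cnt[["inner_lateral"]]),
               unname(targets[["inner"]]))
  expect_equal(unname(cnt[["outer"]]), unname(targets[["outer"]]))
  expect_equal(unname(cnt[["cej"]]), unname(targets[["cej"]]))
  # every inner record has a row id; outer/CEJ never do
  inner <- rec[rec$category %in% c("inner_mesial", "inner_lateral"), ]
  expect_true(all(!is.na(inner$true_row_id)))
  expect_true(all(is.na(rec$true_row_id[rec$category %in% c("outer", "cej")])))
  expect_equal(length(unique(inner$true_row_id)), cfg$n_rows)
  # adjacent rows alternate tilt
  tilt_by_row <- inner |>
    dplyr::distinct(true_row_id, tilt) |>
    dplyr::arrange(true_row_id)
  expect_true(all(tilt_by_row$tilt[-1] != tilt_by_row$tilt[-cfg$n_rows]))
})

test_that("two rows of ten alternate tilt in the minimal layout", {
  cfg <- rod_config(total_profiles = 20, n_rows = 2, band_width_um = 52,
                    category_fractions = c(inner = 1, outer = 0, cej = 0))
  rec <- sample_rod_layout(cfg, build_band_geometry(cfg))
  expect_equal(nrow(rec), 20)
  expect_equal(unname(table(rec$true_row_id)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_setequal(unique(rec$tilt), c("mesial", "lateral"))
})

test_that("degenerate angular noise yields the configured angle exactly", {
  const90 <- lapply(
    list(inner_mesial = 1, inner_lateral = 1, outer = 1, cej = 1),
    function(.) list(mean = rep(90, 4), sd = rep(1e-9, 4)))
  cfg <- small_config(seed = 32, angle_field = const90)
  rec <- sample_rod_layout(cfg, build_band_geometry(cfg))
  expect_true(all(abs(rec$true_angle_deg - 90) < 1e-6))
  # noiseless pooled recovery: measured circular mean within 0.5 degrees
  map <- render_color_maps(rec, build_band_geometry(cfg))
  an <- run_pipeline(map)
  expect_lt(ang_diff(circular_mean(an$rods$feret_angle_deg)$mean_deg, 90),
            0.5)
})

test_that("rendering produces one component per record inside the band", {
  cfg <- small_config(total_profiles = 120, n_rows = 6, seed = 33)
  geom <- build_band_geometry(cfg)
  rec <- sample_rod_layout(cfg, geom)
  map <- render_color_maps(rec, geom)
  for (cat in CATS) {
    n_comp <- attr(extract_particles(map$layers[[cat]]), "n")
    expect_identical(n_comp, sum(rec$category == cat))
  }
  # empty record list: four blank layers
  blank <- render_color_maps(NULL, geom)
  expect_true(all(vapply(blank$layers, function(l) sum(l) == 0, logical(1))))
  # a record outside the band is refused with its id
  bad <- rec[1, ]
  bad$true_y_px <- geom$height_px + 50
  expect_error(render_color_maps(bad, geom), "outside")
  # overlapping records are refused
  twice <- rec[c(1, 1), ]
  expect_error(render_color_maps(twice, geom), "overlap")
})

test_that("rendered profiles recover centroid and orientation", {
  # long thin profiles: orientation precision grows with the aspect ratio,
  # so these make the per-profile tolerances meaningful
  cfg <- rod_config(total_profiles = 32, n_rows = 4, band_width_um = 120,
                    category_fractions = c(inner = 1, outer = 0, cej = 0),
                    spacing_field = list(inner_mesial = rep(10, 4),
                                         inner_lateral = rep(10, 4),
                                         outer = rep(4, 4),
                                         cej = rep(4, 4)),
                    shapes = list(ellipse_axes_um = c(long = 8, short = 1)),
                    lane_margin_um = 30, seed = 34)
  map <- simulate_enamel_map(cfg)
  an <- run_pipeline(map)
  tr <- map$truth
  inner_m <- dplyr::filter(an$rods, category == "inner_mesial")
  tr_m <- dplyr::filter(tr, category == "inner_mesial")
  idx <- match_to_truth(inner_m$centroid_x, inner_m$centroid_y,
                        tr_m$true_x_px, tr_m$true_y_px)
  expect_false(anyNA(idx))
  dx <- inner_m$centroid_x - tr_m$true_x_px[idx]
  dy <- inner_m$centroid_y - tr_m$true_y_px[idx]
  expect_true(all(sqrt(dx^2 + dy^2) < 1))
  err <- ang_diff(inner_m$feret_angle_deg, tr_m$true_angle_deg[idx])
  expect_true(all(err < 2)) # axis ratio >= 2
})

test_that("generation is reproducible and infeasible packing is refused", {
  cfg <- small_config(seed = 35)
  r1 <- sample_rod_layout(cfg, build_band_geometry(cfg))
  r2 <- sample_rod_layout(cfg, build_band_geometry(cfg))
  expect_identical(r1, r2)
  m1 <- simulate_enamel_map(cfg)
  m2 <- simulate_enamel_map(cfg)
  expect_identical(m1$layers, m2$layers)
  over <- small_config(total_profiles = 100000)
  expect_error(simulate_enamel_map(over), "limiting region")
})
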