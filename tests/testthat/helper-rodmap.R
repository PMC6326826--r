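# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

CATS <- c("inner_mesial", "inner_lateral", "outer", "cej")

# A small, fast band configuration (same architecture as the default, fewer
# lanes and a shorter band).
small_config <- function(total_profiles = 400, n_rows = 12,
                         band_width_um = 112, seed = 1L, ...) {
  rod_config(total_profiles = total_profiles, n_rows = n_rows,
             band_width_um = band_width_um, seed = seed, ...)
}

# Brute-force Feret oracle: exhaustive rotation of the pixel-corner point
# set in `step`-degree increments; returns max and min caliper widths.
feret_brute <- function(xs, ys, step = 0.1) {
  cx <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  th <- seq(0, 180 - step, by = step) * pi / 180
  widths <- vapply(th, function(a) {
    p <- cx * cos(a) + cy * sin(a)
    max(p) - min(p)
  }, numeric(1))
  c(max = max(widths), min = min(widths))
}

# Random 8-connected pixel blob of ~n pixels (random walk with duplicates
# removed).
random_blob <- function(n = 30) {
  x <- y <- integer(n * 3)
  x[1] <- 50L; y[1] <- 50L
  for (i in 2:(n * 3)) {
    d <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    x[i] <- x[i - 1] + d[1]; y[i] <- y[i - 1] + d[2]
  }
  keep <- !duplicated(cbind(x, y))
  cbind(x = x[keep][seq_len(min(n, sum(keep)))],
        y = y[keep][seq_len(min(n, sum(keep)))])
}

# Rasterise one ellipse (semi-axes in px, angle in degrees) onto a blank
# matrix, independent of the package's renderer.
raster_ellipse <- function(H, W, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  m <- matrix(FALSE, H, W)
  g <- expand.grid(row = 1:H, col = 1:W)
  dx <- (g$col - 0.5) - cx
  dy <- (H - g$row + 0.5) - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  m[cbind(g$row, g$col)] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Directional circular mean in degrees (independent recomputation).
circ_mean_oracle <- function(a) {
  r <- a * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

# Smallest absolute difference between two directions, degrees.
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Match measured centroids to ground-truth centroids by proximity (grid
# lookup; truth and measurement differ by well under a pixel). Returns the
# index of the matched truth record for every measured point.
match_to_truth <- function(mx, my, tx, ty) {
  key <- function(x, y) paste(floor(x), floor(y))
  lut <- split(seq_along(tx), key(tx, ty))
  vapply(seq_along(mx), function(i) {
    cand <- integer()
    for (ddx in -1:1) for (ddy in -1:1) {
      cand <- c(cand, lut[[key(mx[i] + ddx, my[i] + ddy)]])
    }
    if (length(cand) == 0) return(NA_integer_)
    cand[which.min((tx[cand] - mx[i])^2 + (ty[cand] - my[i])^2)]
  }, integer(1))
}
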