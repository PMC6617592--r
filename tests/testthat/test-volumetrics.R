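test_that("cross-section area matches hand trapezoid oracles", {
  # rectangle: constant 160 mm over a 300 mm swath
  lat <- seq(0, 300, by = 50)
  expect_equal(cross_section_area(rep(160, length(lat)), lat), 48000)
  # all zero
  expect_equal(cross_section_area(rep(0, 7), lat), 0)
  # triangle {0, 100, 0} at {-150, 0, 150}
  expect_equal(cross_section_area(c(0, 100, 0), c(-150, 0, 150)), 15000)
  # fewer than two valid samples
  expect_equal(cross_section_area(c(NA, 50, NA), c(-1, 0, 1)), 0)
  expect_equal(cross_section_area(numeric(0), numeric(0)), 0)
  expect_error(cross_section_area(1:3, 1:2),
               class = "swardscan_parameter_error")
})

test_that("isolated no-returns are bridged, edge no-returns truncate", {
  lat <- c(0, 10, 20, 30)
  # interior NA: trapezoid over the remaining samples spans the gap
  expect_equal(cross_section_area(c(10, NA, 10, 10), lat),
               0.5 * (10 + 10) * 20 + 0.5 * (10 + 10) * 10)
  # trailing NA: the last panel is dropped, nothing extrapolated
  expect_equal(cross_section_area(c(10, 10, 10, NA), lat), 200)
})

test_that("the LV equation is mean cross-section area times distance", {
  # n identical integrals A over distance d give A * d for any n
  for (n in c(1, 3, 10)) {
    expect_equal(lidar_volume(rep(7.5, n), distance_mm = 40), 300)
  }
  expect_equal(lidar_volume(c(1, 2, 3), distance_mm = 6), 12)
  expect_equal(lidar_volume(rep(0, 5), distance_mm = 100), 0)
  expect_error(lidar_volume(numeric(0), 10),
               class = "swardscan_empty_plot_error")
  expect_error(lidar_volume(1:3, -1), class = "swardscan_parameter_error")
})

make_ph <- function(m, lat, odo, ground = 0, cut = 0) {
  s <- scan_stream(m, lateral_mm = lat, odometer_mm = odo)
  win <- list(plot_id = 1L, start_mm = min(odo) - 0.5,
              end_mm = max(odo) + 0.5)
  heights_above_cut(s, win, ground, cut)
}

test_that("rasterization bins to cell means and fills gaps by nearest value", {
  lat <- seq(0, 90, by = 10)
  odo <- seq(0, 90, by = 10)
  # uniform field: every cell equals the value, nothing interpolated
  ph <- make_ph(matrix(100, 10, 10), lat, odo)
  g <- rasterize_surface(ph, grid_res_mm = 10)
  expect_true(all(g$z == 100))
  expect_false(any(g$interpolated))
  # two-level field gridded at sample spacing: cell means equal samples
  m <- matrix(rep(c(50, 150), each = 50), 10, 10)
  g2 <- rasterize_surface(make_ph(m, lat, odo), grid_res_mm = 10)
  expect_setequal(unique(as.vector(g2$z)), c(50, 150))
  # a hole is filled from its nearest occupied cell
  m3 <- matrix(100, 10, 10); m3[5, 5] <- NA
  g3 <- rasterize_surface(make_ph(m3, lat, odo), grid_res_mm = 10)
  expect_true(all(g3$z == 100))
  expect_error(rasterize_surface(make_ph(matrix(1, 3, 3), c(0, 1, 2),
                                         c(0, 1, 2)), grid_res_mm = 50),
               class = "swardscan_parameter_error")
})

test_that("surface volume equals the brute-force cell sum", {
  # box: uniform 160 mm over 1000 x 300 mm
  ph <- make_ph(matrix(160, 41, 13), seq(0, 300, length.out = 13),
                seq(0, 1000, length.out = 41))
  g <- rasterize_surface(ph, grid_res_mm = 25)
  expect_equal(surface_volume(g), 160 * 1000 * 300)
  withr::with_seed(21, {
    gz <- g
    gz$z <- matrix(runif(length(g$z)), nrow(g$z))
    brute <- 0
    for (i in seq_len(nrow(gz$z))) {
      for (j in seq_len(ncol(gz$z))) brute <- brute + gz$z[i, j]
    }
    expect_equal(surface_volume(gz), brute * gz$dx * gz$dy)
  })
  zg <- g; zg$z[] <- 0
  expect_equal(surface_volume(zg), 0)
})

test_that("per-scan and raster paths agree: exactly for constant canopies", {
  ph <- make_ph(matrix(160, 41, 13), seq(0, 300, length.out = 13),
                seq(0, 1000, length.out = 41))
  lv <- plot_lv(ph)$lv
  sv <- surface_volume(rasterize_surface(ph, grid_res_mm = 25))
  expect_equal(lv, sv)   # both h * span_x * span_y, no tolerance
})

test_that("per-scan and raster paths agree within 2% on dense smooth plots", {
  x <- seq(0, 2000, by = 10)
  y <- seq(-275, 275, by = 10)
  shapes <- list(
    function(x, y) 300 * exp(-y^2 / (2 * 60^2)),
    function(x, y) 200 + 50 * sin(x / 150) * cos(y / 80),
    function(x, y) pmax(250 - abs(y), 0))
  for (f in shapes) {
    s <- analytic_stream(f, x, y)
    win <- list(plot_id = 1L, start_mm = 0, end_mm = 2001)
    ph <- heights_above_cut(s, win, ground_mm = 0, cutting_height_mm = 0)
    lv <- plot_lv(ph)$lv
    sv <- surface_volume(rasterize_surface(ph, grid_res_mm = 20))
    expect_lt(abs(lv - sv) / sv, 0.02)
  }
})

test_that("LV is linear in canopy height and monotone in the canopy", {
  withr::with_seed(31, {
    m <- matrix(runif(200, 0, 300), 20, 10)
    lat <- seq(-225, 225, length.out = 10)
    odo <- seq(0, 950, length.out = 20)
    base <- plot_lv(make_ph(m, lat, odo))$lv
    for (c in c(0.5, 2, 7)) {
      expect_equal(plot_lv(make_ph(c * m, lat, odo))$lv, c * base,
                   tolerance = 1e-12)
    }
    bigger <- m + matrix(runif(200, 0, 50), 20, 10)
    expect_gte(plot_lv(make_ph(bigger, lat, odo))$lv, base)
  })
})

test_that("LV is invariant to scan rate at fixed canopy and coverage", {
  f <- function(x, y) 250 * exp(-y^2 / (2 * 70^2)) * (1 + 0.1 * sin(x / 300))
  y <- seq(-275, 275, by = 5)
  win <- list(plot_id = 1L, start_mm = 0, end_mm = 2000.5)
  lv_at <- function(dx) {
    x <- seq(0, 2000, by = dx)
    ph <- heights_above_cut(analytic_stream(f, x, y), win, 0, 0)
    plot_lv(ph)$lv
  }
  # doubling the along-track line density changes LV by < 1%
  expect_lt(abs(lv_at(10) - lv_at(5)) / lv_at(5), 0.01)
  expect_lt(abs(lv_at(20) - lv_at(10)) / lv_at(10), 0.01)
})

test_that("empty and sparse plots are flagged, not zeroed", {
  m <- matrix(NA_real_, 4, 3)
  ph <- make_ph(m, c(0, 10, 20), c(0, 1, 2, 3))
  out <- plot_lv(ph)
  expect_equal(out$status, "empty")
  expect_true(is.na(out$lv))
})
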