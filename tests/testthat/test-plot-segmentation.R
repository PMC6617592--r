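flat_stream <- function(span_mm, n_lines = 50, h = 0) {
  scan_stream(matrix(h, n_lines, 3), lateral_mm = c(-100, 0, 100),
              odometer_mm = seq(0, span_mm, length.out = n_lines))
}

test_that("a 36 m column splits into 18 windows of 2 m", {
  cfg <- field_config(36000, 18, 550, 40)
  w <- segment_column(flat_stream(36000), cfg)
  expect_equal(nrow(w), 18)
  expect_equal(unique(w$end_mm - w$start_mm), 2000)
  expect_equal(sum(w$end_mm - w$start_mm), 36000)
  # disjoint ordered tiling
  expect_equal(w$start_mm[-1], w$end_mm[-18])
})

test_that("segmentation boundaries honour the first odometer position", {
  cfg <- field_config(10000, 4, 550, 40)
  s <- scan_stream(matrix(0, 40, 2), lateral_mm = c(0, 100),
                   odometer_mm = seq(500, 10400, length.out = 40))
  w <- segment_column(s, cfg)
  expect_equal(w$start_mm, c(500, 3000, 5500, 8000))
  expect_equal(w$end_mm, c(3000, 5500, 8000, 10500))

  one <- segment_column(flat_stream(10000), field_config(10000, 1, 550, 40))
  expect_equal(nrow(one), 1)
  expect_equal(one$end_mm - one$start_mm, 10000)
})

test_that("a stream far shorter than the declared scan length is refused", {
  cfg <- field_config(36000, 18, 550, 40)
  expect_error(segment_column(flat_stream(20000), cfg), "shortfall",
               class = "swardscan_coverage_error")
  # 5% odometer drift is tolerated
  expect_silent(segment_column(flat_stream(34500), cfg))
})

test_that("segment length must be exact to the millimetre", {
  expect_error(field_config(10000, 3, 550, 40),
               class = "swardscan_config_error")
})

test_that("manual offsets shift windows and re-validate disjointness", {
  cfg <- field_config(10000, 5, 550, 40)
  w <- segment_column(flat_stream(10000), cfg)
  expect_identical(apply_manual_offsets(w, NULL), w)
  same <- apply_manual_offsets(w, tibble::tibble(plot_id = 1:5, offset_mm = 0))
  expect_equal(same$start_mm, w$start_mm)

  ok <- apply_manual_offsets(w, tibble::tibble(plot_id = 5, offset_mm = 100))
  expect_equal(ok$start_mm[5], w$start_mm[5] + 100)
  expect_equal(ok$manual_offset_mm[5], 100)

  expect_error(
    apply_manual_offsets(w, tibble::tibble(plot_id = 2, offset_mm = -3000)),
    "overlap", class = "swardscan_geometry_error")
  expect_error(
    apply_manual_offsets(w, tibble::tibble(plot_id = 99, offset_mm = 1)),
    class = "swardscan_parameter_error")
})

test_that("ground is the low quantile of valid in-window heights", {
  expect_equal(estimate_ground(rep(0, 50), 0.05), 0)
  expect_equal(estimate_ground(rep(50, 20), 0.3), 50)
  # 95 soil samples at 0, 5 canopy at 100: the 5th percentile stays on soil
  h <- c(rep(0, 95), rep(100, 5))
  expect_equal(estimate_ground(h, 0.05), 0)
  # agreement with the sort-based definition: with n = 101 the 5th
  # percentile position (n - 1) * p + 1 = 6 is an exact order statistic
  withr::with_seed(9, {
    v <- runif(101, -30, 400)
    expect_equal(estimate_ground(v, 0.05), sort(v)[6])
    # and interpolation between order statistics otherwise
    v4 <- c(10, 0, 30, 20)
    expect_equal(estimate_ground(v4, 0.5), 15)
  })
  expect_warning(g <- estimate_ground(c(NA_real_, NA_real_)), "empty")
  expect_true(is.na(g))
})

test_that("heights above the cut follow the clipped affine rule", {
  s <- scan_stream(matrix(c(100, 120, 160), 1), lateral_mm = c(-50, 0, 50),
                   odometer_mm = 0)
  win <- list(plot_id = 1L, start_mm = -1, end_mm = 1)
  ph <- heights_above_cut(s, win, ground_mm = 100, cutting_height_mm = 40)
  expect_equal(ph$h_plus, c(0, 0, 20))
  expect_true(all(ph$h_plus >= 0))

  # boundary: height exactly at ground + cut
  ph0 <- heights_above_cut(s, win, ground_mm = 60, cutting_height_mm = 40)
  expect_equal(ph0$h_plus[1], 0)
  # affine: 160 above the threshold
  ph1 <- heights_above_cut(s, win, ground_mm = 100, cutting_height_mm = 0)
  expect_equal(ph1$h_plus, c(0, 20, 60))
  expect_error(heights_above_cut(s, win, 0, -1),
               class = "swardscan_parameter_error")
})

test_that("h+ is invariant under datum shifts and antitone in the cut", {
  withr::with_seed(11, {
    m <- matrix(runif(60, 0, 300), 5, 12)
    lat <- seq(-250, 250, length.out = 12)
    win <- list(plot_id = 1L, start_mm = 0, end_mm = 100)
    for (shift in c(-137.5, 0, 42)) {
      s0 <- scan_stream(m, lat, odometer_mm = seq(0, 99, length.out = 5))
      s1 <- scan_stream(m + shift, lat, odometer_mm = seq(0, 99, length.out = 5))
      a <- heights_above_cut(s0, win, 50, 40)$h_plus
      b <- heights_above_cut(s1, win, 50 + shift, 40)$h_plus
      expect_equal(a, b, tolerance = 1e-10)
    }
    cuts <- c(0, 20, 40, 80, 1000)
    s0 <- scan_stream(m, lat, odometer_mm = seq(0, 99, length.out = 5))
    hp <- lapply(cuts, function(ct) heights_above_cut(s0, win, 50, ct)$h_plus)
    for (i in seq_along(cuts)[-1]) {
      expect_true(all(hp[[i]] <= hp[[i - 1]] + 1e-12))
    }
  })
})

test_that("boundary scans belong to exactly one half-open window", {
  cfg <- field_config(4000, 2, 550, 40)
  s <- scan_stream(matrix(0, 5, 2), lateral_mm = c(0, 1),
                   odometer_mm = c(0, 1000, 2000, 3000, 3999))
  w <- segment_column(s, cfg)
  in1 <- stream_window(s, w[1, ])
  in2 <- stream_window(s, w[2, ])
  # odometer 2000 sits in window 2 only
  expect_equal(unique(in1$odometer_mm), c(0, 1000))
  expect_equal(unique(in2$odometer_mm), c(2000, 3000, 3999))
  expect_equal(nrow(in1) + nrow(in2), nrow(s))
})
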