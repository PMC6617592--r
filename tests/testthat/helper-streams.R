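# Small in-code fixtures shared across the suite.

# random stream with heights on the 0.1 mm grid (the on-disk precision)
# and a sprinkling of invalid samples
random_stream <- function(seed, n_lines = 8, n_samples = 6, na_frac = 0.1) {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n_lines * n_samples, 0, 500), 1),
                n_lines, n_samples)
    m[runif(length(m)) < na_frac] <- NA_real_
    scan_stream(m,
                lateral_mm = sort(round(runif(n_samples, -300, 300), 1)),
                odometer_mm = cumsum(round(runif(n_lines, 0, 50), 1)),
                datum_note = "test datum",
                meta = list(rate_hz = "270", speed_mm_s = "500"))
  })
}

# stream sampled from an analytic height field h(x, y) on a regular grid
analytic_stream <- function(h, x, y) {
  scan_stream(outer(x, y, h), lateral_mm = y, odometer_mm = x)
}

expect_stream_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$height_mm, b$height_mm, tolerance = tol)
  expect_equal(a$lateral_mm, b$lateral_mm, tolerance = tol)
  expect_equal(a$odometer_mm, b$odometer_mm, tolerance = tol)
  expect_equal(a$line, b$line)
  expect_equal(stream_lateral_grid(a), stream_lateral_grid(b),
               tolerance = tol)
}

# the 100-plot mixed-canopy recovery study: 5 columns of 20 plots,
# 2 m x 550 mm geometry, 40 mm cut
recovery_study <- function(seed, noise_sd_mm = 5, dropout_p = 0.02,
                           ground_amplitude_mm = 20) {
  cfg <- field_config(40000, 20, 550, 40)
  purrr::map_dfr(1:5, function(col) {
    can <- random_canopies(20, seed = seed + col, row_spacing_mm = 550)
    sim <- simulate_field(cfg, can,
                          ground_amplitude_mm = ground_amplitude_mm,
                          noise_sd_mm = noise_sd_mm, dropout_p = dropout_p,
                          seed = seed + 100 + col)
    res <- process_stream(sim$stream, cfg)$results
    dplyr::inner_join(res, sim$truth, by = "plot_id")
  })
}
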