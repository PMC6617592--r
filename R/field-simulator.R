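#' Parametric canopy models
#'
#' One simulated plot carries one canopy profile, constant along-track and
#' parametric across the row:
#'
#' * `canopy_box(height_mm, width_mm)` — a rectangular sward of uniform
#'   height over a centred band of the given width (an idealized dense,
#'   evenly grazed row);
#' * `canopy_ridge(peak_mm, sigma_mm)` — a Gaussian ridge
#'   `z(y) = peak * exp(-y^2 / (2 sigma^2))` (a single row with a rounded
#'   crown tapering into the inter-row gap);
#' * `canopy_bare()` — bare soil.
#'
#' @param height_mm,peak_mm Canopy height / ridge peak above ground (mm,
#'   >= 0).
#' @param width_mm,sigma_mm Band width / ridge standard deviation (mm, > 0).
#' @return A one-row tibble describing the canopy; bind rows to build a
#'   column of plots.
#' @examples
#' dplyr::bind_rows(canopy_box(200, 300), canopy_ridge(300, 60), canopy_bare())
#' @export
canopy_box <- function(height_mm, width_mm) {
  stopifnot(height_mm >= 0, width_mm > 0)
  tibble(kind = "box", height_mm = height_mm, width_mm = width_mm,
         peak_mm = NA_real_, sigma_mm = NA_real_)
}

#' @rdname canopy_box
#' @export
canopy_ridge <- function(peak_mm, sigma_mm) {
  stopifnot(peak_mm >= 0, sigma_mm > 0)
  tibble(kind = "gaussian_ridge", height_mm = NA_real_, width_mm = NA_real_,
         peak_mm = peak_mm, sigma_mm = sigma_mm)
}

#' @rdname canopy_box
#' @export
canopy_bare <- function() {
  tibble(kind = "box", height_mm = 0, width_mm = 1,
         peak_mm = NA_real_, sigma_mm = NA_real_)
}

# canopy profile evaluated on a lateral grid; returns a height vector
canopy_profile <- function(model, y) {
  switch(model$kind,
         box = ifelse(abs(y) <= model$width_mm / 2, model$height_mm, 0),
         gaussian_ridge = model$peak_mm * exp(-y^2 / (2 * model$sigma_mm^2)),
         abort(sprintf("unknown canopy kind '%s'", model$kind),
               class = "swardscan_parameter_error"))
}

#' Analytic canopy volume above the virtual cut
#'
#' Closed form for the box canopy; adaptive quadrature
#' (`stats::integrate`) of `max(z(y) - cut, 0)` for the Gaussian ridge.
#' The canopy is constant along-track, so the volume is the cross-section
#' integral times the plot length. A cut at or above the canopy top gives 0.
#'
#' @param model A one-row canopy tibble ([canopy_box()] /
#'   [canopy_ridge()]).
#' @param cutting_height_mm Virtual cutting height (mm, >= 0).
#' @param length_mm Along-track plot length (mm).
#' @param swath_mm Lateral extent observed by the scanner (mm); the
#'   integral is restricted to `[-swath/2, swath/2]`. Default `Inf`.
#' @return Volume above the cut in mm^3.
#' @export
truth_volume <- function(model, cutting_height_mm, length_mm,
                         swath_mm = Inf) {
  stopifnot(cutting_height_mm >= 0, length_mm > 0)
  half <- swath_mm / 2
  if (model$kind == "box") {
    w <- min(model$width_mm, swath_mm)
    return(max(model$height_mm - cutting_height_mm, 0) * w * length_mm)
  }
  if (model$kind == "gaussian_ridge") {
    if (model$peak_mm <= cutting_height_mm) return(0)
    f <- function(y) {
      pmax(model$peak_mm * exp(-y^2 / (2 * model$sigma_mm^2)) -
             cutting_height_mm, 0)
    }
    lim <- if (is.finite(half)) half else
      model$sigma_mm * sqrt(2 * log(model$peak_mm /
                                      max(cutting_height_mm, 1e-12))) + 1
    area <- integrate(f, -lim, lim, rel.tol = 1e-9,
                      subdivisions = 500L)$value
    return(area * length_mm)
  }
  abort(sprintf("unknown canopy kind '%s'", model$kind),
        class = "swardscan_parameter_error")
}

#' Simulate a scanned column over parametric canopies
#'
#' Generates a synthetic [scan_stream()] emulating the line-scan sensing
#' geometry: lines at regular along-track spacing, a fixed lateral sample
#' grid spanning the row spacing, heights composed of a slowly undulating
#' ground sinusoid plus the per-plot canopy profile plus Gaussian sensor
#' noise, and Bernoulli no-return dropouts. Along-track and lateral sample
#' spacings are equal and chosen to hit the requested point density. The
#' analytic volume of every canopy above the virtual cut is returned
#' alongside, so pipeline output can be scored against ground truth.
#'
#' The default density, 7,000 points/m^2, is a 100x reduction of the
#' instrument-class density (700,000 points/m^2) for desk-scale work; pass
#' the full density explicitly to study convergence. A request implying
#' more than 10^7 samples is refused.
#'
#' @param config A [field_config()]; one canopy per segment is required.
#' @param canopies A canopy tibble with `segments_per_scan` rows (see
#'   [canopy_box()]).
#' @param ground_amplitude_mm Amplitude of the ground sinusoid (mm).
#' @param ground_wavelength_mm Wavelength of the ground sinusoid (mm).
#' @param noise_sd_mm SD of Gaussian height noise (mm, >= 0).
#' @param dropout_p Per-sample probability of a no-return, in `[0, 1)`.
#' @param point_density_m2 Target sample density (points per m^2).
#' @param seed Integer RNG seed (mandatory; the stream is bit-reproducible
#'   given the seed).
#' @param ground_offset_mm Constant added to the ground profile (datum
#'   shift; default 0).
#' @return A list with `stream` (a `scan_stream`) and `truth` (a tibble
#'   `plot_id`, `kind`, `true_volume_mm3`).
#' @examples
#' cfg <- field_config(4000, 2, 300, 40, ma_window = 3)
#' sim <- simulate_field(cfg, dplyr::bind_rows(canopy_box(200, 200),
#'                                             canopy_ridge(300, 50)),
#'                       noise_sd_mm = 0, dropout_p = 0, seed = 1)
#' sim$truth
#' @export
simulate_field <- function(config, canopies,
                           ground_amplitude_mm = 20,
                           ground_wavelength_mm = 20000,
                           noise_sd_mm = 5,
                           dropout_p = 0.02,
                           point_density_m2 = 7000,
                           seed,
                           ground_offset_mm = 0) {
  stopifnot(inherits(config, "field_config"))
  if (missing(seed)) {
    abort("`seed` is mandatory: simulated streams must be reproducible.",
          class = "swardscan_parameter_error")
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    abort("`dropout_p` must lie in [0, 1).",
          class = "swardscan_parameter_error")
  }
  if (noise_sd_mm < 0) {
    abort("`noise_sd_mm` must be >= 0.", class = "swardscan_parameter_error")
  }
  if (nrow(canopies) != config$segments_per_scan) {
    abort(sprintf("need one canopy per segment: %d segments but %d canopies.",
                  config$segments_per_scan, nrow(canopies)),
          class = "swardscan_parameter_error")
  }
  spacing <- sqrt(1e6 / point_density_m2)   # mm between samples, both axes
  half <- config$row_spacing_mm / 2
  y_pos <- seq(0, half, by = spacing)
  y <- c(-rev(y_pos[-1]), y_pos)
  x <- seq(0, config$scan_length_mm - spacing / 2, by = spacing)
  n_total <- length(x) * length(y)
  if (n_total > 1e7) {
    abort(sprintf(
      "requested density implies %.3g samples (> 1e7); reduce density or scan length.",
      n_total), class = "swardscan_size_error")
  }
  seg_len <- config$scan_length_mm / config$segments_per_scan
  plot_of_x <- pmin(floor(x / seg_len) + 1L, config$segments_per_scan)
  ground <- ground_offset_mm +
    ground_amplitude_mm * sin(2 * pi * x / ground_wavelength_mm)

  m <- matrix(0, nrow = length(x), ncol = length(y))
  for (p in seq_len(config$segments_per_scan)) {
    rows <- which(plot_of_x == p)
    prof <- canopy_profile(canopies[p, ], y)
    m[rows, ] <- matrix(prof, nrow = length(rows), ncol = length(y),
                        byrow = TRUE)
  }
  m <- m + ground   # recycles ground down the rows (columns vary slowest)
  withr::with_seed(seed, {
    if (noise_sd_mm > 0) {
      m <- m + matrix(rnorm(n_total, 0, noise_sd_mm), nrow = length(x))
    }
    if (dropout_p > 0) {
      m[runif(n_total) < dropout_p] <- NA_real_
    }
  })
  stream <- scan_stream(
    m, lateral_mm = y, odometer_mm = x,
    datum_note = "synthetic field datum (mean ground level = ground_offset_mm)",
    meta = list(point_density_m2 = point_density_m2,
                spacing_mm = spacing, seed = seed,
                noise_sd_mm = noise_sd_mm, dropout_p = dropout_p,
                ground_amplitude_mm = ground_amplitude_mm,
                ground_wavelength_mm = ground_wavelength_mm))
  truth <- tibble(
    plot_id = seq_len(config$segments_per_scan),
    kind = canopies$kind,
    true_volume_mm3 = vapply(seq_len(nrow(canopies)), function(i) {
      truth_volume(canopies[i, ], config$cutting_height_mm, seg_len,
                   swath_mm = config$row_spacing_mm)
    }, numeric(1)))
  list(stream = stream, truth = truth)
}

#' Draw a realistic mixed column of canopies
#'
#' Convenience generator for simulation studies: alternating box swards
#' and Gaussian ridges with canopy heights drawn uniformly from
#' 150-750 mm (a five-fold range, spanning lax regrowth to pre-grazing
#' covers), box widths 27-55% of the row spacing and ridge SDs 7-13% of
#' it, so inter-row soil stays visible to the ground estimator.
#'
#' @param n Number of plots.
#' @param seed Integer RNG seed.
#' @param row_spacing_mm Lateral row spacing (mm) the widths scale with.
#' @return An `n`-row canopy tibble (see [canopy_box()]).
#' @export
random_canopies <- function(n, seed, row_spacing_mm = 550) {
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(n), function(i) {
      h <- runif(1, 150, 750)
      if (i %% 2 == 1) {
        canopy_box(h, runif(1, 0.27, 0.55) * row_spacing_mm)
      } else {
        canopy_ridge(h, runif(1, 0.07, 0.13) * row_spacing_mm)
      }
    }))
  })
}
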