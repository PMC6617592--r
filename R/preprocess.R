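#' Rectify polar range readings to lateral/height samples
#'
#' Line-scan units report a distance per beam angle. With the scanner at
#' `sensor_height_mm` above the datum and angles measured from nadir
#' (radians, positive to the right), a return at range `r` and angle `a`
#' rectifies to `lateral_mm = r * sin(a)` and
#' `height_mm = sensor_height_mm - r * cos(a)`. Zero or negative ranges are
#' no-return samples and map to `NA`.
#'
#' @param ranges Numeric vector of measured distances (mm).
#' @param angles Numeric vector of beam angles from nadir (radians), same
#'   length as `ranges`.
#' @param sensor_height_mm Scanner height above the datum (mm).
#' @return A tibble with columns `lateral_mm`, `height_mm` (one row per
#'   beam, in input order).
#' @examples
#' polar_to_heights(c(1000, 1000, 0), c(0, pi / 6, 0.1), 1000)
#' @export
polar_to_heights <- function(ranges, angles, sensor_height_mm) {
  if (length(ranges) != length(angles)) {
    abort("`ranges` and `angles` must have equal length.",
          class = "swardscan_parameter_error")
  }
  invalid <- !is.finite(ranges) | ranges <= 0
  lateral <- ranges * sin(angles)
  height <- sensor_height_mm - ranges * cos(angles)
  lateral[invalid] <- NA_real_
  height[invalid] <- NA_real_
  tibble(lateral_mm = lateral, height_mm = height)
}

#' Flag and count invalid (no-return) samples
#'
#' Invalid samples never contribute to ground estimation or volume
#' integrals; their lateral grid positions are retained (as `NA` heights)
#' so line geometry is preserved. This pass leaves the data unchanged —
#' invalid samples are already excluded by every downstream computation —
#' and produces the bookkeeping report: how many samples are invalid, how
#' many lines are touched, and which lines carry no valid sample at all
#' (zero evidence; such lines still count towards the scan count of their
#' plot but contribute zero cross-section area).
#'
#' @param stream A [scan_stream()].
#' @return A list with elements `stream` (unchanged) and `report`, a
#'   one-row tibble with `n_invalid_removed`, `lines_touched`,
#'   `n_empty_lines`.
#' @export
drop_invalid <- function(stream) {
  m <- as_height_matrix(stream)
  inv <- is.na(m)
  per_line <- rowSums(inv)
  report <- tibble(
    n_invalid_removed = sum(inv),
    lines_touched = sum(per_line > 0),
    n_empty_lines = sum(per_line == ncol(m)))
  list(stream = stream, report = report)
}

#' Smooth scan lines with a moving average along the lateral axis
#'
#' Each valid height is replaced by the mean of the valid heights inside a
#' centered window along its own scan line ("the direction of the scan").
#' Invalid samples neither contribute to nor receive smoothed values, and
#' windows are truncated at line ends rather than padded, so no data is
#' invented beyond the swath. `window = 1` is the identity.
#'
#' @param stream A [scan_stream()].
#' @param window Odd positive window width in samples.
#' @return A smoothed `scan_stream` with the same geometry and invalid
#'   pattern.
#' @export
moving_average <- function(stream, window) {
  window <- check_ma_window(window)
  if (window == 1L) return(stream)
  m <- as_height_matrix(stream)
  scan_stream(ma_rows(m, window),
              lateral_mm = stream_lateral_grid(stream),
              odometer_mm = stream_odometer(stream),
              line = stream$line[seq(1, nrow(stream),
                                     by = length(stream_lateral_grid(stream)))],
              datum_note = attr(stream, "datum_note"),
              meta = stream_meta(stream))
}

# NA-skipping centered moving average along the rows of a matrix, window
# truncated at the edges; computed from running sums for all rows at once.
ma_rows <- function(m, window) {
  half <- (window - 1L) %/% 2L
  n <- ncol(m)
  valid <- !is.na(m)
  v <- ifelse(valid, m, 0)
  # cumulative sums across columns, prepended with a zero column
  cs_v <- cbind(0, t(apply(v, 1, cumsum)))
  cs_c <- cbind(0, t(apply(valid, 1, cumsum)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sums <- cs_v[, hi + 1L, drop = FALSE] - cs_v[, lo, drop = FALSE]
  cnts <- cs_c[, hi + 1L, drop = FALSE] - cs_c[, lo, drop = FALSE]
  out <- sums / cnts          # NaN where a window holds no valid sample
  out[!valid] <- NA_real_     # invalid samples receive nothing
  out[valid & cnts == 0] <- NA_real_   # unreachable, kept for safety
  out
}

#' Run the standard pre-processing pass
#'
#' Applies [drop_invalid()] bookkeeping followed by [moving_average()]
#' with the configured window, and attaches the filter report (including
#' the window used) to the returned stream as attribute `filter_report`.
#'
#' @param stream A [scan_stream()].
#' @param config A [field_config()] (its `ma_window` is used).
#' @return The smoothed `scan_stream` with a `filter_report` attribute.
#' @export
preprocess_stream <- function(stream, config) {
  stopifnot(inherits(config, "field_config"))
  res <- drop_invalid(stream)
  out <- moving_average(res$stream, config$ma_window)
  attr(out, "filter_report") <- mutate(res$report,
                                       window_used = config$ma_window)
  out
}
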