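#' Segment a scanned column into fixed-geometry plot windows
#'
#' Splits the along-track axis into `segments_per_scan` equal, half-open
#' windows tiling `[first_odometer, first_odometer + scan_length_mm)`. Plots
#' in row trials have fixed sown geometry, so segmentation is by distance,
#' not by vegetation gaps; manual offsets correct the occasional misaligned
#' plot ([apply_manual_offsets()]).
#'
#' The stream must cover at least 95% of the declared scan length
#' (odometer drift tolerance); a shorter stream raises a coverage error
#' stating the shortfall.
#'
#' @param stream A [scan_stream()].
#' @param config A [field_config()].
#' @return A tibble of plot windows: `plot_id`, `start_mm`, `end_mm`
#'   (half-open `[start, end)`), `manual_offset_mm` (0).
#' @examples
#' cfg <- field_config(36000, 18, 550, 40)
#' s <- scan_stream(matrix(0, 10, 3), c(-100, 0, 100),
#'                  seq(0, 36000, length.out = 10))
#' segment_column(s, cfg)
#' @export
segment_column <- function(stream, config) {
  stopifnot(inherits(stream, "scan_stream"), inherits(config, "field_config"))
  span <- stream_span(stream)
  if (span < 0.95 * config$scan_length_mm) {
    abort(sprintf(
      "stream spans %.0f mm but the configuration declares %.0f mm (shortfall %.0f mm); cannot segment.",
      span, config$scan_length_mm, config$scan_length_mm - span),
      class = "swardscan_coverage_error")
  }
  seg_len <- config$scan_length_mm / config$segments_per_scan
  first <- stream_odometer(stream)[1]
  starts <- first + seg_len * (seq_len(config$segments_per_scan) - 1)
  tibble(plot_id = seq_len(config$segments_per_scan),
         start_mm = starts,
         end_mm = starts + seg_len,
         manual_offset_mm = 0)
}

#' Apply manual along-track offsets to plot windows
#'
#' Shifts each window by its signed correction and re-validates that the
#' shifted windows remain disjoint. Offsets are keyed by `plot_id`;
#' plots without an entry are unchanged.
#'
#' @param windows A window tibble from [segment_column()].
#' @param offsets A tibble with columns `plot_id`, `offset_mm`
#'   (see [read_offsets()]).
#' @return The shifted window tibble with `manual_offset_mm` updated.
#' @export
apply_manual_offsets <- function(windows, offsets) {
  if (is.null(offsets) || nrow(offsets) == 0) return(windows)
  unknown <- setdiff(offsets$plot_id, windows$plot_id)
  if (length(unknown) > 0) {
    abort(sprintf("offsets refer to unknown plot_id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "swardscan_parameter_error")
  }
  shifted <- windows |>
    left_join(offsets, by = "plot_id") |>
    mutate(offset_mm = ifelse(is.na(.data$offset_mm), 0, .data$offset_mm),
           start_mm = .data$start_mm + .data$offset_mm,
           end_mm = .data$end_mm + .data$offset_mm,
           manual_offset_mm = .data$manual_offset_mm + .data$offset_mm) |>
    select(-"offset_mm") |>
    arrange(.data$start_mm)
  overlap <- which(shifted$end_mm[-nrow(shifted)] > shifted$start_mm[-1])
  if (length(overlap) > 0) {
    pairs <- paste0(shifted$plot_id[overlap], "/", shifted$plot_id[overlap + 1])
    abort(sprintf("manual offsets make plot windows overlap: %s",
                  paste(pairs, collapse = ", ")),
          class = "swardscan_geometry_error")
  }
  shifted
}

#' Estimate the ground height of one plot
#'
#' Ground level varies between plots in field trials, so it is estimated
#' per plot as a low quantile (linear interpolation between order
#' statistics) of all valid heights in the plot window: inter-row soil and
#' canopy gaps populate the low tail of the height distribution even under
#' a dense canopy.
#'
#' @param heights Numeric vector of heights in the window (`NA` = invalid).
#' @param ground_percentile Quantile in (0, 1); default 0.05.
#' @return The ground height (mm, stream datum), or `NA` with a warning if
#'   the window holds no valid sample (empty plot).
#' @export
estimate_ground <- function(heights, ground_percentile = 0.05) {
  heights <- heights[!is.na(heights)]
  if (length(heights) == 0) {
    warn("plot window holds no valid sample; ground is undefined (empty plot).")
    return(NA_real_)
  }
  unname(quantile(heights, probs = ground_percentile, type = 7))
}

#' Segment grass from soil at the virtual cutting height
#'
#' Converts raw heights of the lines inside one plot window into heights
#' above the virtual cut: `h+ = max(height - ground - cutting_height, 0)`.
#' Heights at or below ground plus cut (soil, residual stubble) contribute
#' nothing, mimicking the residual left by mechanical defoliation. Invalid
#' samples stay `NA`.
#'
#' @param stream A [scan_stream()] (typically pre-processed).
#' @param window One row of a window tibble (`plot_id`, `start_mm`,
#'   `end_mm`), or a list with those fields.
#' @param ground_mm Ground estimate for the plot (from [estimate_ground()]).
#' @param cutting_height_mm Virtual cutting height (mm, >= 0).
#' @return A `plot_heights` tibble: the window's samples with an added
#'   `h_plus` column; attributes `window`, `ground_mm`,
#'   `cutting_height_mm`, `lateral_grid`.
#' @export
heights_above_cut <- function(stream, window, ground_mm, cutting_height_mm) {
  if (cutting_height_mm < 0) {
    abort("`cutting_height_mm` must be >= 0.",
          class = "swardscan_parameter_error")
  }
  sub <- stream_window(stream, window)
  sub$h_plus <- pmax(sub$height_mm - ground_mm - cutting_height_mm, 0)
  structure(sub,
            window = as.list(window[c("plot_id", "start_mm", "end_mm")]),
            ground_mm = ground_mm,
            cutting_height_mm = cutting_height_mm,
            lateral_grid = stream_lateral_grid(stream),
            class = c("plot_heights", class(tibble())))
}

# samples of the lines whose odometer falls in [start_mm, end_mm)
stream_window <- function(stream, window) {
  keep <- stream$odometer_mm >= window$start_mm &
    stream$odometer_mm < window$end_mm
  out <- as_tibble(stream)[keep, ]
  attr(out, "lateral_grid") <- stream_lateral_grid(stream)
  out
}
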