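#' Field processing configuration
#'
#' Bundles the geometry and processing parameters that drive plot
#' segmentation and volumetrics: the along-track scan length of one column,
#' how many equal plot segments it is divided into, the row spacing (the
#' lateral swath the scanner covers), and the virtual cutting height above
#' ground below which vegetation is ignored (mimicking the residual left by
#' mechanical defoliation).
#'
#' The along-track segment length `scan_length_mm / segments_per_scan` must
#' come out to a whole millimetre; otherwise plot boundaries would drift
#' along a column and an error is raised.
#'
#' @param scan_length_mm Along-track length of one scanned column (mm), > 0.
#' @param segments_per_scan Number of equal plot segments per column, >= 1.
#' @param row_spacing_mm Lateral row spacing / swath width (mm), > 0.
#' @param cutting_height_mm Virtual cutting height above estimated ground
#'   (mm), >= 0. Heights at or below ground + cut contribute no volume.
#' @param ground_percentile Quantile of valid in-window heights used as the
#'   per-plot ground estimate, in (0, 1). Default 0.05: inter-row soil and
#'   canopy gaps populate the low tail of the height distribution.
#' @param ma_window Odd moving-average window (samples) applied along the
#'   lateral axis of each scan line. Default 5.
#' @param grid_res_mm Cell size (mm) of the diagnostic raster-surface path.
#' @param lv_scale Multiplier applied to the reported LV index. LV is
#'   computed internally in mm^3-equivalent units; the published index is
#'   unitless, so a scale factor lets users match legacy magnitudes.
#'   Default 1.
#'
#' @return An object of class `field_config` (a named list).
#' @examples
#' field_config(scan_length_mm = 36000, segments_per_scan = 18,
#'              row_spacing_mm = 550, cutting_height_mm = 40)
#' @export
field_config <- function(scan_length_mm,
                         segments_per_scan,
                         row_spacing_mm,
                         cutting_height_mm,
                         ground_percentile = 0.05,
                         ma_window = 5,
                         grid_res_mm = 25,
                         lv_scale = 1) {
  if (!is.numeric(scan_length_mm) || length(scan_length_mm) != 1 ||
      !is.finite(scan_length_mm) || scan_length_mm <= 0) {
    abort("`scan_length_mm` must be a single positive number.",
          class = "swardscan_config_error")
  }
  if (!is.numeric(segments_per_scan) || length(segments_per_scan) != 1 ||
      segments_per_scan < 1 || segments_per_scan != round(segments_per_scan)) {
    abort("`segments_per_scan` must be a whole number >= 1.",
          class = "swardscan_config_error")
  }
  if (!is.numeric(row_spacing_mm) || row_spacing_mm <= 0) {
    abort("`row_spacing_mm` must be positive.",
          class = "swardscan_config_error")
  }
  if (!is.numeric(cutting_height_mm) || cutting_height_mm < 0) {
    abort("`cutting_height_mm` must be >= 0.",
          class = "swardscan_config_error")
  }
  if (!is.numeric(ground_percentile) || ground_percentile <= 0 ||
      ground_percentile >= 1) {
    abort("`ground_percentile` must lie strictly between 0 and 1.",
          class = "swardscan_config_error")
  }
  check_ma_window(ma_window)
  if (!is.numeric(grid_res_mm) || grid_res_mm <= 0) {
    abort("`grid_res_mm` must be positive.",
          class = "swardscan_config_error")
  }
  seg_len <- scan_length_mm / segments_per_scan
  if (abs(seg_len - round(seg_len)) > 1e-9) {
    abort(sprintf(
      "scan_length_mm / segments_per_scan = %.6f mm is not a whole millimetre; plot boundaries would drift.",
      seg_len), class = "swardscan_config_error")
  }
  structure(
    list(scan_length_mm = as.numeric(scan_length_mm),
         segments_per_scan = as.integer(segments_per_scan),
         row_spacing_mm = as.numeric(row_spacing_mm),
         cutting_height_mm = as.numeric(cutting_height_mm),
         ground_percentile = as.numeric(ground_percentile),
         ma_window = as.integer(ma_window),
         grid_res_mm = as.numeric(grid_res_mm),
         lv_scale = as.numeric(lv_scale)),
    class = "field_config")
}

check_ma_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    abort("moving-average `window` must be a positive odd integer.",
          class = "swardscan_parameter_error")
  }
  invisible(as.integer(window))
}

#' @export
print.field_config <- function(x, ...) {
  cat("<field_config>\n")
  cat(sprintf("  scan length     %g mm in %d segments of %g mm\n",
              x$scan_length_mm, x$segments_per_scan,
              x$scan_length_mm / x$segments_per_scan))
  cat(sprintf("  row spacing     %g mm\n", x$row_spacing_mm))
  cat(sprintf("  cutting height  %g mm above ground\n", x$cutting_height_mm))
  cat(sprintf("  ground quantile %g, MA window %d, grid %g mm, lv scale %g\n",
              x$ground_percentile, x$ma_window, x$grid_res_mm, x$lv_scale))
  invisible(x)
}

#' Read or write a field configuration as a key-value file
#'
#' The file is plain YAML whose keys mirror the [field_config()] argument
#' names, e.g. `scan_length_mm: 36000`.
#'
#' @param path File path.
#' @return `read_field_config()` returns a `field_config`;
#'   `write_field_config()` returns `path` invisibly.
#' @export
read_field_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "swardscan_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(field_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown config keys: %s",
                 paste(extra, collapse = ", ")))
  }
  do.call(field_config, vals[intersect(names(vals), known)])
}

#' @param config A `field_config`.
#' @rdname read_field_config
#' @export
write_field_config <- function(config, path) {
  stopifnot(inherits(config, "field_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
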