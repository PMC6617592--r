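#' Scan streams
#'
#' A scan stream is the raw sensor record of one scanned column: an ordered
#' sequence of scan lines, each at an along-track odometer position, each
#' holding a fixed lateral grid of height samples. In memory it is a long
#' tibble with one row per sample and columns
#'
#' * `line` — ordinal line index (0-based, as recorded),
#' * `odometer_mm` — along-track position of the line (non-decreasing),
#' * `lateral_mm` — lateral offset from the scan centreline (strictly
#'   increasing within a line; identical grid for every line),
#' * `height_mm` — height above the stream's datum, or `NA` for a
#'   no-return (invalid) sample.
#'
#' Attributes carry the shared lateral grid (`lateral_grid`), a free-text
#' `datum_note`, and a named `meta` list (scan rate, platform speed, point
#' density, ...).
#'
#' @param heights Numeric matrix of heights, one row per scan line, one
#'   column per lateral sample; `NA` marks invalid samples.
#' @param lateral_mm Strictly increasing numeric vector of lateral sample
#'   positions (mm), length `ncol(heights)`.
#' @param odometer_mm Non-decreasing numeric vector of along-track positions
#'   (mm), length `nrow(heights)`.
#' @param line Optional integer line indices (default `0:(nlines-1)`).
#' @param datum_note Free text describing the height datum.
#' @param meta Named list of header metadata.
#'
#' @return A tibble of class `scan_stream`.
#' @examples
#' scan_stream(matrix(c(0, 10, 5, 0, 12, 4), nrow = 2, byrow = TRUE),
#'             lateral_mm = c(-100, 0, 100), odometer_mm = c(0, 10))
#' @export
scan_stream <- function(heights, lateral_mm, odometer_mm,
                        line = NULL, datum_note = "", meta = list()) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (is.null(line)) line <- seq_len(nrow(heights)) - 1L
  validate_stream_geometry(lateral_mm, odometer_mm, nrow(heights),
                           ncol(heights), length(line))
  out <- tibble(
    line = rep(as.integer(line), each = ncol(heights)),
    odometer_mm = rep(as.numeric(odometer_mm), each = ncol(heights)),
    lateral_mm = rep(as.numeric(lateral_mm), times = nrow(heights)),
    height_mm = as.numeric(t(heights)))
  new_scan_stream(out, lateral_grid = as.numeric(lateral_mm),
                  datum_note = datum_note, meta = meta)
}

new_scan_stream <- function(df, lateral_grid, datum_note = "", meta = list()) {
  structure(df,
            lateral_grid = lateral_grid,
            datum_note = datum_note,
            meta = meta,
            class = c("scan_stream", class(tibble())))
}

validate_stream_geometry <- function(lateral_mm, odometer_mm,
                                     n_lines, n_samples, n_index) {
  if (n_lines < 1) {
    abort("a scan stream needs at least one line.",
          class = "swardscan_geometry_error")
  }
  if (length(lateral_mm) != n_samples || n_samples < 1) {
    abort("lateral grid length must match the sample count (>= 1).",
          class = "swardscan_geometry_error")
  }
  if (any(diff(lateral_mm) <= 0)) {
    abort("lateral_mm must be strictly increasing within a scan line.",
          class = "swardscan_geometry_error")
  }
  if (length(odometer_mm) != n_lines || n_index != n_lines) {
    abort("odometer and line-index lengths must match the line count.",
          class = "swardscan_geometry_error")
  }
  if (any(diff(odometer_mm) < 0)) {
    abort("odometer_mm must be non-decreasing with line index.",
          class = "swardscan_geometry_error")
  }
  invisible(TRUE)
}

#' Stream accessors
#'
#' `stream_lateral_grid()`, `stream_meta()` and `stream_span()` expose the
#' shared lateral grid, header metadata and along-track span
#' (last odometer minus first) of a [scan_stream()].
#'
#' @param stream A `scan_stream`.
#' @return A numeric vector, named list, or single number respectively.
#' @export
stream_lateral_grid <- function(stream) attr(stream, "lateral_grid")

#' @rdname stream_lateral_grid
#' @export
stream_meta <- function(stream) attr(stream, "meta") %||% list()

#' @rdname stream_lateral_grid
#' @export
stream_span <- function(stream) {
  odo <- stream_odometer(stream)
  odo[length(odo)] - odo[1]
}

# per-line odometer vector (one entry per line, in line order)
stream_odometer <- function(stream) {
  n_samp <- length(stream_lateral_grid(stream))
  stream$odometer_mm[seq(1, nrow(stream), by = n_samp)]
}

stream_n_lines <- function(stream) {
  nrow(stream) / length(stream_lateral_grid(stream))
}

# heights as a lines x samples matrix; inverse of scan_stream()
as_height_matrix <- function(stream) {
  n_samp <- length(stream_lateral_grid(stream))
  matrix(stream$height_mm, ncol = n_samp, byrow = TRUE)
}

#' Normalize a serpentine-scanned column to increasing odometer
#'
#' Columns scanned on the return leg of a serpentine pass record decreasing
#' odometer positions. Segmentation assumes non-decreasing odometer, so such
#' streams are reversed line-for-line first; the odometer values themselves
#' are kept (only their order flips).
#'
#' @param stream A `scan_stream` whose odometer is monotone in either
#'   direction.
#' @return A `scan_stream` with non-decreasing odometer; attribute
#'   `reversed` records whether a flip happened.
#' @export
normalize_serpentine <- function(stream) {
  n_samp <- length(stream_lateral_grid(stream))
  odo <- stream$odometer_mm[seq(1, nrow(stream), by = n_samp)]
  reversed <- FALSE
  if (any(diff(odo) < 0)) {
    if (any(diff(odo) > 0)) {
      abort("odometer is neither non-decreasing nor non-increasing; cannot normalize.",
            class = "swardscan_geometry_error")
    }
    m <- matrix(stream$height_mm, ncol = n_samp, byrow = TRUE)
    stream <- scan_stream(m[rev(seq_len(nrow(m))), , drop = FALSE],
                          lateral_mm = stream_lateral_grid(stream),
                          odometer_mm = rev(odo),
                          datum_note = attr(stream, "datum_note"),
                          meta = stream_meta(stream))
    reversed <- TRUE
  }
  attr(stream, "reversed") <- reversed
  stream
}

#' @export
print.scan_stream <- function(x, ...) {
  n_samp <- length(stream_lateral_grid(x))
  cat(sprintf("<scan_stream> %d lines x %d samples, span %.1f mm, %d invalid\n",
              stream_n_lines(x), n_samp, stream_span(x),
              sum(is.na(x$height_mm))))
  NextMethod()
}

#' Export a stream as an XYZ point-cloud table
#'
#' One row per valid sample with `x` = along-track odometer position, `y` =
#' lateral offset and `z` = height, all in mm. Invalid (no-return) samples
#' are omitted, so the output may be empty.
#'
#' @param stream A `scan_stream`.
#' @return A tibble with columns `x`, `y`, `z` (mm).
#' @export
export_xyz <- function(stream) {
  out <- tibble(x = stream$odometer_mm, y = stream$lateral_mm,
                z = stream$height_mm)
  out[!is.na(out$z), ]
}
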