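#' Cross-section area of one scan line above the virtual cut
#'
#' Trapezoidal integral of `h+` over the lateral axis of one line, taken
#' across the valid samples: consecutive valid samples are connected even
#' when an isolated no-return lies between them, so an invalid sample does
#' not delete the canopy around it (strict panel exclusion would bias the
#' integral low by twice the no-return rate). Leading and trailing invalid
#' samples truncate the integration range — nothing is invented beyond the
#' observed swath. Lines with fewer than two valid samples have zero area
#' (sparse line).
#'
#' @param h_plus Numeric vector of heights above the cut (mm, `NA` =
#'   invalid), ordered along the lateral grid.
#' @param lateral_mm The lateral grid (mm), strictly increasing, same
#'   length.
#' @return Area in mm^2.
#' @examples
#' cross_section_area(c(0, 100, 0), c(-150, 0, 150))  # 15000
#' @export
cross_section_area <- function(h_plus, lateral_mm) {
  if (length(h_plus) != length(lateral_mm)) {
    abort("`h_plus` and `lateral_mm` must have equal length.",
          class = "swardscan_parameter_error")
  }
  ok <- !is.na(h_plus)
  if (sum(ok) < 2) return(0)
  h <- h_plus[ok]
  lat <- lateral_mm[ok]
  sum(0.5 * (h[-length(h)] + h[-1]) * diff(lat))
}

#' The LiDAR Volume index
#'
#' The per-plot biomass proxy: the per-scan cross-section integrals are
#' summed, multiplied by the distance travelled across the plot, and
#' divided by the number of scans —
#' `LV = (sum of integrals) * distance / n_scans`, i.e. the mean
#' cross-section area times the travel distance. Dividing by the scan count
#' makes the index invariant to scan rate, so plots scanned at different
#' platform speeds or rates remain comparable.
#'
#' @param per_scan_integrals Numeric vector of per-line cross-section areas
#'   (mm^2).
#' @param distance_mm Along-track distance actually covered by the scans
#'   (mm, >= 0).
#' @param n_scans Number of scan lines (defaults to
#'   `length(per_scan_integrals)`).
#' @return The LV index (internally mm^3).
#' @examples
#' lidar_volume(c(1, 2, 3), distance_mm = 6)  # 12
#' @export
lidar_volume <- function(per_scan_integrals, distance_mm,
                         n_scans = length(per_scan_integrals)) {
  if (n_scans < 1) {
    abort("LV is undefined for an empty plot (no scans).",
          class = "swardscan_empty_plot_error")
  }
  if (distance_mm < 0) {
    abort("`distance_mm` must be >= 0.", class = "swardscan_parameter_error")
  }
  sum(per_scan_integrals) * distance_mm / n_scans
}

#' Compute the LV result for one segmented plot
#'
#' Integrates each scan line of a [heights_above_cut()] plot and applies
#' the LV equation. The distance is the span of odometer positions actually
#' observed inside the window, not the nominal window length, so partially
#' covered plots are not extrapolated; `coverage` reports the observed
#' fraction of the window.
#'
#' @param ph A `plot_heights` object.
#' @param lv_scale Multiplier for the reported index (default 1).
#' @return A one-row tibble: `plot_id`, `n_scans`, `distance_mm`,
#'   `ground_mm`, `lv`, `coverage`, `status` (`"ok"`, `"sparse"` or
#'   `"empty"`), plus list-column `per_scan_integrals`.
#' @export
plot_lv <- function(ph, lv_scale = 1) {
  stopifnot(inherits(ph, "plot_heights"))
  win <- attr(ph, "window")
  lateral <- attr(ph, "lateral_grid")
  n_samp <- length(lateral)
  if (nrow(ph) == 0 || all(is.na(ph$h_plus))) {
    return(tibble(plot_id = win$plot_id, n_scans = nrow(ph) %/% max(n_samp, 1),
                  distance_mm = NA_real_, ground_mm = attr(ph, "ground_mm"),
                  lv = NA_real_, coverage = 0, status = "empty",
                  per_scan_integrals = list(numeric(0))))
  }
  m <- matrix(ph$h_plus, ncol = n_samp, byrow = TRUE)
  areas <- apply(m, 1, cross_section_area, lateral_mm = lateral)
  odo <- ph$odometer_mm[seq(1, nrow(ph), by = n_samp)]
  distance <- max(odo) - min(odo)
  nominal <- win$end_mm - win$start_mm
  n_valid_per_line <- rowSums(!is.na(m))
  status <- if (mean(n_valid_per_line >= 2) < 0.5) "sparse" else "ok"
  tibble(plot_id = win$plot_id,
         n_scans = nrow(m),
         distance_mm = distance,
         ground_mm = attr(ph, "ground_mm"),
         lv = lidar_volume(areas, distance) * lv_scale,
         coverage = distance / nominal,
         status = status,
         per_scan_integrals = list(areas))
}

#' Rasterize a plot's canopy into a surface grid
#'
#' The independent integration path: `h+` samples are binned onto a regular
#' (along-track x lateral) grid covering the observed extent, each cell
#' taking the mean of its samples; empty cells are filled by
#' nearest-neighbour interpolation and flagged in the `interpolated` mask.
#' This reconstructs the canopy as a 3D surface whose volume
#' ([surface_volume()]) cross-checks the per-scan-integral LV path.
#'
#' @param ph A `plot_heights` object with at least one valid sample.
#' @param grid_res_mm Target cell size (mm); the extent is divided into a
#'   whole number of cells of approximately this size.
#' @return A `surface_grid`: list with matrix `z` (rows = along-track
#'   cells, cols = lateral cells), logical matrix `interpolated`, cell
#'   dimensions `dx`, `dy` (mm) and cell-center coordinates.
#' @export
rasterize_surface <- function(ph, grid_res_mm) {
  stopifnot(inherits(ph, "plot_heights"))
  ok <- !is.na(ph$h_plus)
  if (!any(ok)) {
    abort("plot has no valid sample; cannot rasterize.",
          class = "swardscan_empty_plot_error")
  }
  x <- ph$odometer_mm[ok]
  y <- ph$lateral_mm[ok]
  z <- ph$h_plus[ok]
  span_x <- max(x) - min(x)
  span_y <- max(y) - min(y)
  nx <- max(round(span_x / grid_res_mm), 1)
  ny <- max(round(span_y / grid_res_mm), 1)
  if (nx < 2 || ny < 2) {
    abort("grid resolution is coarser than the plot (need >= 2 cells per axis).",
          class = "swardscan_parameter_error")
  }
  dx <- span_x / nx
  dy <- span_y / ny
  ix <- pmin(pmax(floor((x - min(x)) / dx) + 1, 1), nx)
  iy <- pmin(pmax(floor((y - min(y)) / dy) + 1, 1), ny)
  zmat <- matrix(NA_real_, nx, ny)
  agg <- rowsum(cbind(z, 1), group = (iy - 1) * nx + ix)
  cells <- as.integer(rownames(agg))
  zmat[cells] <- agg[, 1] / agg[, 2]
  interp <- is.na(zmat)
  if (any(interp)) {
    zmat <- fill_nearest(zmat, dx, dy)
  }
  structure(list(z = zmat, interpolated = interp, dx = dx, dy = dy,
                 x_mm = min(x) + (seq_len(nx) - 0.5) * dx,
                 y_mm = min(y) + (seq_len(ny) - 0.5) * dy),
            class = "surface_grid")
}

# nearest-neighbour fill of NA cells using physical cell-center distances
fill_nearest <- function(zmat, dx, dy) {
  nx <- nrow(zmat); ny <- ncol(zmat)
  filled <- which(!is.na(zmat), arr.ind = TRUE)
  empty <- which(is.na(zmat), arr.ind = TRUE)
  if (nrow(filled) == 0) {
    abort("surface grid has no occupied cell.",
          class = "swardscan_empty_plot_error")
  }
  fx <- filled[, 1] * dx; fy <- filled[, 2] * dy
  vals <- zmat[filled]
  for (k in seq_len(nrow(empty))) {
    d2 <- (fx - empty[k, 1] * dx)^2 + (fy - empty[k, 2] * dy)^2
    zmat[empty[k, 1], empty[k, 2]] <- vals[which.min(d2)]
  }
  zmat
}

#' Volume under a rasterized canopy surface
#'
#' Sum of cell heights times cell area: the 3D-surface integral of `h+`
#' over the plot.
#'
#' @param grid A `surface_grid` from [rasterize_surface()].
#' @return Volume in mm^3.
#' @export
surface_volume <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  sum(grid$z) * grid$dx * grid$dy
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d cells of %.1f x %.1f mm, %d interpolated\n",
              nrow(x$z), ncol(x$z), x$dx, x$dy, sum(x$interpolated)))
  invisible(x)
}
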