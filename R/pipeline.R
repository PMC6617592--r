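#' Process one scanned column end-to-end
#'
#' The production pipeline from raw stream to per-plot LV: serpentine
#' normalization, invalid-return bookkeeping, lateral moving-average
#' smoothing, fixed-geometry segmentation (plus manual offsets),
#' per-plot ground estimation at the configured quantile, height
#' segmentation at the virtual cutting height, and the LV equation.
#' Empty plots (no valid sample) are flagged, not silently zeroed.
#'
#' @param stream A [scan_stream()].
#' @param config A [field_config()].
#' @param offsets Optional manual-offset tibble (`plot_id`, `offset_mm`).
#' @param column_id Optional column label carried into the results.
#' @return A list with
#'   * `results` — one row per plot: `plot_id`, `column_id`, `n_scans`,
#'     `distance_mm`, `ground_mm`, `lv`, `coverage`, `status`,
#'     list-column `per_scan_integrals`;
#'   * `manifest` — config snapshot, filter report and per-plot status
#'     flags (see [write_manifest()]).
#' @examples
#' cfg <- field_config(4000, 2, 300, 40, ma_window = 3)
#' sim <- simulate_field(cfg, dplyr::bind_rows(canopy_box(200, 200),
#'                                             canopy_box(400, 200)),
#'                       noise_sd_mm = 0, dropout_p = 0,
#'                       ground_amplitude_mm = 0, seed = 1)
#' process_stream(sim$stream, cfg)$results
#' @export
process_stream <- function(stream, config, offsets = NULL,
                           column_id = NA_character_) {
  stopifnot(inherits(stream, "scan_stream"), inherits(config, "field_config"))
  stream <- normalize_serpentine(stream)
  reversed <- isTRUE(attr(stream, "reversed"))
  stream <- preprocess_stream(stream, config)
  windows <- segment_column(stream, config)
  if (!is.null(offsets)) windows <- apply_manual_offsets(windows, offsets)

  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    win <- windows[i, ]
    sub <- stream_window(stream, win)
    ground <- withCallingHandlers(
      estimate_ground(sub$height_mm, config$ground_percentile),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(ground)) {
      return(tibble(plot_id = win$plot_id, n_scans = 0L,
                    distance_mm = NA_real_, ground_mm = NA_real_,
                    lv = NA_real_, coverage = 0, status = "empty",
                    per_scan_integrals = list(numeric(0))))
    }
    ph <- heights_above_cut(stream, win, ground, config$cutting_height_mm)
    plot_lv(ph, lv_scale = config$lv_scale)
  })
  results <- bind_rows(rows) |>
    mutate(column_id = column_id, .after = "plot_id") |>
    mutate(status = ifelse(.data$status == "ok" &
                             windows$manual_offset_mm != 0,
                           "manual-offset", .data$status))
  manifest <- list(
    package_version = as.character(packageVersion("swardscan")),
    column_id = column_id,
    config = unclass(config),
    serpentine_reversed = reversed,
    filter_report = as.list(attr(stream, "filter_report")),
    plots = setNames(as.list(results$status), results$plot_id))
  list(results = results, manifest = manifest)
}

#' Process a scan file into a results CSV and manifest
#'
#' Thin file-level wrapper over [read_scan_text()] and [process_stream()].
#'
#' @param scan_path Path to a scan text file.
#' @param config A [field_config()].
#' @param offsets_path Optional manual-offsets CSV (see [read_offsets()]).
#' @param out_csv Optional results CSV path (written when supplied).
#' @param manifest_path Optional manifest JSON path.
#' @return The [process_stream()] result, invisibly when writing files.
#' @export
process_scan_file <- function(scan_path, config, offsets_path = NULL,
                              out_csv = NULL, manifest_path = NULL) {
  stream <- read_scan_text(scan_path)
  offsets <- if (!is.null(offsets_path)) read_offsets(offsets_path)
  res <- process_stream(stream, config, offsets,
                        column_id = basename(scan_path))
  res$manifest$inputs <- list(scan = scan_path, offsets = offsets_path)
  if (!is.null(out_csv)) write_results_csv(res$results, out_csv)
  if (!is.null(manifest_path)) write_manifest(res$manifest, manifest_path)
  if (is.null(out_csv) && is.null(manifest_path)) res else invisible(res)
}

#' Write a run manifest as JSON
#'
#' The manifest records the configuration snapshot, input paths, filter
#' report and one status flag per processed plot (`ok` / `sparse` /
#' `empty` / `manual-offset`), keeping provenance out of the data files so
#' result CSVs stay byte-reproducible.
#'
#' @param manifest Manifest list from [process_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Join LV results with harvest traits and summarise
#'
#' The analysis stage: joins per-plot LV results to a harvest trait table
#' by plot id, computes percent dry matter per plot, the trait summary
#' (mean, sample SD, CV%) for FW, DW, %DM and LV, and the calibration
#' regression of LV on fresh weight.
#'
#' @param results LV results (tibble with `plot_id`, `lv`), e.g. from
#'   [process_stream()] or a results CSV.
#' @param traits Trait table with `plot_id`, `fw_g`, `dw_g` (see
#'   [read_trait_table()]).
#' @param by Join key (default `"plot_id"`).
#' @return A list with
#'   * `records` — the joined per-plot tibble with `pdm` columns,
#'   * `summary` — one row per trait: `trait`, `mean`, `sd`, `cv_percent`,
#'     `n`,
#'   * `fit` — the [linear_fit()] of `lv` on `fw_g` (NULL if < 2 rows
#'     join).
#' @export
analyze_traits <- function(results, traits, by = "plot_id") {
  results <- as_tibble(results)
  traits <- as_tibble(traits)
  missing_ids <- setdiff(traits[[by]], results[[by]])
  if (length(missing_ids) > 0) {
    warn(sprintf("trait rows with no LV result: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  rec <- inner_join(results, traits, by = by)
  if (nrow(rec) < 2) {
    abort(sprintf("only %d row(s) join on '%s'; need at least 2.",
                  nrow(rec), by),
          class = "swardscan_domain_error")
  }
  rec <- bind_cols(rec, percent_dm(rec$fw_g, rec$dw_g))
  summary <- bind_rows(
    fw_g = coefficient_of_variation(rec$fw_g),
    dw_g = coefficient_of_variation(rec$dw_g),
    pdm = coefficient_of_variation(rec$pdm),
    lv = coefficient_of_variation(rec$lv),
    .id = "trait")
  fit <- linear_fit(rec, x = "fw_g", y = "lv")
  list(records = rec, summary = summary, fit = fit)
}
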