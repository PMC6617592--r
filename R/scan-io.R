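#' Read a scan stream from its text dialect
#'
#' The on-disk dialect is self-describing plain text. Header lines are
#' `#`-prefixed and declare, in any order after the magic first line:
#'
#' ```
#' # swardscan v1
#' # datum: <free text>
#' # meta: <key>=<value>            (repeatable)
#' # n_samples: <integer>
#' # lateral_mm: <v1> <v2> ... <vn>
#' ```
#'
#' Each body row is whitespace-separated: line index, odometer position
#' (mm), then `n_samples` height values (mm, 0.1 mm precision) with the
#' token `NA` marking a no-return sample. Malformed rows are reported with
#' their file line numbers.
#'
#' @param path Path to a scan text file.
#' @return A validated [scan_stream()].
#' @export
read_scan_text <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scan file not found: %s", path),
          class = "swardscan_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  is_header <- startsWith(trimws(raw), "#")
  header <- trimws(sub("^\\s*#\\s?", "", raw[is_header]))
  body_idx <- which(!is_header)

  if (length(header) == 0 || !grepl("^swardscan", header[1])) {
    abort("not a swardscan scan file (missing '# swardscan v1' header).",
          class = "swardscan_format_error")
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), header, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  n_samples <- as.integer(get_field("n_samples"))
  lateral_raw <- get_field("lateral_mm")
  if (is.null(n_samples) || is.na(n_samples) || is.null(lateral_raw)) {
    abort("header must declare 'n_samples' and 'lateral_mm'.",
          class = "swardscan_format_error")
  }
  lateral <- as.numeric(strsplit(lateral_raw, "\\s+")[[1]])
  if (length(lateral) != n_samples || anyNA(lateral)) {
    abort(sprintf("lateral grid has %d values but n_samples is %d.",
                  length(lateral), n_samples),
          class = "swardscan_format_error")
  }
  datum_note <- get_field("datum") %||% ""
  meta_lines <- grep("^meta:", header, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(trimws(sub("^meta:", "", m)), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }

  if (length(body_idx) == 0) {
    abort("scan file has no body rows.", class = "swardscan_format_error")
  }
  tokens <- strsplit(trimws(raw[body_idx]), "\\s+")
  widths <- lengths(tokens)
  bad <- widths != n_samples + 2L
  if (any(bad)) {
    # map back to original file line numbers for the report
    file_lines <- which(nzchar(trimws(readLines(path, warn = FALSE))))
    abad <- file_lines[!is_header][bad]
    abort(sprintf(
      "ragged body rows (expected %d fields) at file line(s): %s",
      n_samples + 2L, paste(head(abad, 10), collapse = ", ")),
      class = "swardscan_format_error")
  }
  flat <- suppressWarnings(as.numeric(unlist(tokens)))
  m <- matrix(flat, ncol = n_samples + 2L, byrow = TRUE)
  # any non-numeric token other than NA would also appear as NA; only the
  # height columns may legitimately carry NA
  if (anyNA(m[, 1:2])) {
    abort("non-numeric line index or odometer value in body.",
          class = "swardscan_format_error")
  }
  odo <- m[, 2]
  reversed <- FALSE
  if (any(diff(odo) < 0)) {
    if (any(diff(odo) > 0)) {
      abort("odometer positions are not monotone within the file.",
            class = "swardscan_geometry_error")
    }
    # return leg of a serpentine pass: store lines in increasing-odometer order
    ord <- rev(seq_len(nrow(m)))
    m <- m[ord, , drop = FALSE]
    odo <- odo[ord]
    reversed <- TRUE
  }
  out <- scan_stream(m[, -(1:2), drop = FALSE], lateral_mm = lateral,
                     odometer_mm = odo, line = as.integer(m[, 1]),
                     datum_note = datum_note, meta = meta)
  attr(out, "reversed") <- reversed
  out
}

#' Write a scan stream in the text dialect
#'
#' Heights and positions are written to 0.1 mm so that
#' `read_scan_text(write_scan_text(s))` reproduces `s` field-for-field at
#' the declared precision.
#'
#' @param stream A [scan_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_text <- function(stream, path) {
  stopifnot(inherits(stream, "scan_stream"))
  lateral <- stream_lateral_grid(stream)
  meta <- stream_meta(stream)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) {
                    abort(sprintf("cannot open '%s' for writing: %s",
                                  path, conditionMessage(e)),
                          class = "swardscan_io_error")
                  })
  on.exit(close(con))
  writeLines(c(
    "# swardscan v1",
    paste0("# datum: ", attr(stream, "datum_note") %||% ""),
    if (length(meta) > 0)
      paste0("# meta: ", names(meta), "=", unlist(meta)),
    paste0("# n_samples: ", length(lateral)),
    paste0("# lateral_mm: ", paste(fmt_mm(lateral), collapse = " "))),
    con)
  m <- as_height_matrix(stream)
  odo <- stream_odometer(stream)
  idx <- stream$line[seq(1, nrow(stream), by = length(lateral))]
  body <- paste(idx, fmt_mm(odo),
                apply(m, 1, function(r) paste(fmt_mm(r), collapse = " ")))
  writeLines(body, con)
  invisible(path)
}

fmt_mm <- function(x) {
  out <- sprintf("%.1f", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read and write plot trait tables
#'
#' Trait tables are CSV with columns `plot_id`, `fw_g` (fresh weight,
#' g/row) and `dw_g` (dry weight, g/row); extra columns are kept.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trait_table <- function(path) {
  df <- as_tibble(read.csv(path, check.names = TRUE))
  need <- c("plot_id", "fw_g", "dw_g")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("trait table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "swardscan_format_error")
  }
  df
}

#' Read a manual plot-offset table
#'
#' CSV with columns `plot_id` and `offset_mm`: signed along-track
#' corrections applied to the fixed-geometry plot windows (used when plots
#' are sparsely populated or poorly separated).
#'
#' @param path CSV path.
#' @return A tibble with columns `plot_id`, `offset_mm`.
#' @export
read_offsets <- function(path) {
  df <- as_tibble(read.csv(path))
  miss <- setdiff(c("plot_id", "offset_mm"), names(df))
  if (length(miss) > 0) {
    abort(sprintf("offsets table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "swardscan_format_error")
  }
  df
}

#' Write per-plot LV results as CSV
#'
#' Columns: `plot_id`, `column_id`, `n_scans`, `distance_mm`, `ground_mm`,
#' `lv` (plus `status` and `coverage`). List-columns (per-scan integrals)
#' are dropped from the file.
#'
#' @param results An LV results tibble from [process_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  keep <- !vapply(results, is.list, logical(1))
  write.csv(results[keep], path, row.names = FALSE)
  invisible(path)
}
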