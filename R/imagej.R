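# ImageJ "Results" table ingestion.
#
# One row per measured ellipse, "Area" column in square inches (ImageJ is
# calibrated from the scan DPI). Zero-area "fake" measurements are sentinels
# inserted at ring boundaries to delimit years; the final ring is always
# terminated by one.

#' Square-inch to square-millimetre conversion factor (25.4^2)
#' @export
IN2_TO_MM2 <- 645.16

#' Detect the delimiter of an ImageJ Results export
#'
#' ImageJ saves Results as tab-separated `.txt` by default but falls back to
#' CSV content; both occur in practice. The delimiter is whichever split
#' yields a header containing an `Area` column (case-insensitive), tab
#' preferred on a tie.
#'
#' @param path Path to the measurement file.
#' @return `"tab"` or `"comma"`.
#' @export
detect_delimiter <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  has_area <- function(sep) {
    fields <- trimws(strsplit(header, sep, fixed = TRUE)[[1]])
    any(tolower(fields) == "area")
  }
  if (has_area("\t")) return("tab")
  if (has_area(",")) return("comma")
  stop(sprintf("no 'Area' column found in header of %s (tried tab and comma)",
               path), call. = FALSE)
}

#' Read an ImageJ Results measurement file for one core
#'
#' Rows are ingested in file order (oldest ring first). Areas at or below
#' `sentinel_threshold` are flagged as sentinels; all areas are converted
#' from square inches to mm^2. A non-sentinel area below the ambiguity
#' floor triggers a warning, since a stray one-pixel click can record a
#' tiny nonzero value where a sentinel zero was intended.
#'
#' @param path Path to a tab- or comma-delimited Results table with an
#'   `Area` column. The filename stem is the sample ID.
#' @param sentinel_threshold Maximum area (in^2) treated as a sentinel
#'   ("fake") measurement. Default 0: only exact zeros.
#' @param ambiguity_floor Areas (in^2) below this but above the sentinel
#'   threshold draw a warning. Default 1e-5 in^2 (~0.0065 mm^2), below any
#'   plausible duct.
#' @return An object of class `measurement_file` with fields `sample_id`
#'   and `entries` (data frame: `order_index`, `raw_area_in2`, `area_mm2`,
#'   `is_sentinel`).
#' @export
read_measurements <- function(path, sentinel_threshold = 0,
                              ambiguity_floor = 1e-5) {
  delim <- detect_delimiter(path)
  sep <- if (delim == "tab") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  area_col <- which(tolower(trimws(names(tab))) == "area")[1]
  if (is.na(area_col)) {
    stop(sprintf("no 'Area' column in %s", path), call. = FALSE)
  }
  areas <- tab[[area_col]]
  if (!is.numeric(areas) || anyNA(areas)) {
    stop(sprintf("non-numeric Area value in %s", path), call. = FALSE)
  }
  if (any(areas < 0)) {
    stop(sprintf("negative Area value in %s", path), call. = FALSE)
  }
  sample_id <- tools::file_path_sans_ext(basename(path))
  measurement_file(sample_id, areas,
                   sentinel_threshold = sentinel_threshold,
                   ambiguity_floor = ambiguity_floor)
}

#' Construct a measurement file from raw areas
#'
#' Programmatic equivalent of [read_measurements()] for areas already in
#' memory (used heavily by the fixture generator and tests).
#'
#' @param sample_id Sample ID (filename stem), at most 8 characters.
#' @param raw_areas_in2 Ordered vector of areas in square inches, oldest
#'   ring first, sentinel-delimited; the final entry must be a sentinel.
#' @inheritParams read_measurements
#' @return A `measurement_file`.
#' @export
measurement_file <- function(sample_id, raw_areas_in2,
                             sentinel_threshold = 0, ambiguity_floor = 1e-5) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  if (nchar(sample_id) > 8L) {
    stop(sprintf("sample_id '%s' exceeds the 8-character limit", sample_id),
         call. = FALSE)
  }
  raw <- as.numeric(raw_areas_in2)
  if (length(raw) == 0L) {
    stop(sprintf("%s: no measurements", sample_id), call. = FALSE)
  }
  if (anyNA(raw) || any(raw < 0)) {
    stop(sprintf("%s: areas must be non-negative numbers", sample_id),
         call. = FALSE)
  }
  is_sentinel <- raw <= sentinel_threshold
  if (!is_sentinel[length(raw)]) {
    stop(sprintf(
      "%s: unterminated final ring (last measurement is not a sentinel)",
      sample_id), call. = FALSE)
  }
  suspicious <- !is_sentinel & raw < ambiguity_floor
  if (any(suspicious)) {
    warning(sprintf(
      "%s: %d non-sentinel area(s) below %g in^2 (rows %s); verify these are real ducts, not mis-recorded sentinels",
      sample_id, sum(suspicious), ambiguity_floor,
      paste(utils::head(which(suspicious), 5L), collapse = ", ")),
      call. = FALSE)
  }
  entries <- data.frame(
    order_index = seq_along(raw),
    raw_area_in2 = raw,
    area_mm2 = raw * IN2_TO_MM2,
    is_sentinel = is_sentinel
  )
  structure(list(sample_id = sample_id, entries = entries),
            class = "measurement_file")
}

#' @export
print.measurement_file <- function(x, ...) {
  n_sent <- sum(x$entries$is_sentinel)
  cat(sprintf("<measurement_file> %s: %d measurements (%d ducts, %d ring boundaries)\n",
              x$sample_id, nrow(x$entries),
              nrow(x$entries) - n_sent, n_sent))
  invisible(x)
}
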