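# Calendar-year assignment for sentinel-delimited duct measurement streams.
#
# Each ring's ducts are measured oldest-first and terminated by one sentinel
# (zero-area) measurement; two adjacent sentinels encode a ring with no
# ducts, which is also how a missing (locally absent) ring appears. The
# stream therefore splits into exactly one group per sentinel, and group k
# gets year first_year + k.

#' Construct a dated duct table
#'
#' @param sample_id Sample ID.
#' @param first_year Calendar year of the innermost (oldest) measured ring.
#' @param ducts List of numeric vectors, one per consecutive year; each
#'   element holds that year's duct areas in mm^2 (all > 0; a zero-length
#'   vector is a year with no ducts).
#' @return An object of class `dated_duct_table`.
#' @export
dated_duct_table <- function(sample_id, first_year, ducts) {
  if (!is.list(ducts) || length(ducts) == 0L) {
    stop("ducts must be a non-empty list of numeric vectors", call. = FALSE)
  }
  ducts <- lapply(ducts, as.numeric)
  bad <- vapply(ducts, function(a) anyNA(a) || any(a <= 0), logical(1))
  if (any(bad)) {
    stop("duct areas must all be positive (sentinels are never stored)",
         call. = FALSE)
  }
  first_year <- as.integer(first_year)
  structure(
    list(sample_id = sample_id, first_year = first_year,
         years = seq(first_year, by = 1L, length.out = length(ducts)),
         ducts = ducts),
    class = "dated_duct_table"
  )
}

#' @export
print.dated_duct_table <- function(x, ...) {
  cat(sprintf("<dated_duct_table> %s: %d rings (%d-%d), %d ducts\n",
              x$sample_id, length(x$ducts), x$first_year,
              max(x$years), sum(lengths(x$ducts))))
  invisible(x)
}

#' Assign calendar years to sentinel-delimited duct measurements
#'
#' Splits the measurement stream into maximal runs of non-sentinel areas,
#' each terminated by one sentinel; run k (counting from zero) is the ring
#' formed in `first_year + k`. Empty runs (adjacent sentinels) become years
#' with zero ducts — either a true ductless ring or a missing ring; the two
#' cannot be told apart here and are disambiguated against the ring-width
#' record by [verify_alignment()].
#'
#' @param measurements A `measurement_file` (terminal sentinel enforced at
#'   construction).
#' @param first_year Calendar year of the innermost measured ring.
#' @return A `dated_duct_table` with one row per sentinel.
#' @export
assign_years <- function(measurements, first_year) {
  stopifnot(inherits(measurements, "measurement_file"))
  e <- measurements$entries
  if (!any(e$is_sentinel)) {
    stop(sprintf("%s: no sentinel measurements; cannot delimit rings",
                 measurements$sample_id), call. = FALSE)
  }
  ducts <- list()
  current <- numeric(0)
  for (i in seq_len(nrow(e))) {
    if (e$is_sentinel[i]) {
      ducts[[length(ducts) + 1L]] <- current
      current <- numeric(0)
    } else {
      current <- c(current, e$area_mm2[i])
    }
  }
  # measurement_file guarantees the last entry is a sentinel, so no trailing
  # unterminated run can be silently lost
  dated_duct_table(measurements$sample_id, first_year, ducts)
}

#' Cross-check a dated duct table against the ring-width record
#'
#' Returns a report rather than raising, so users can fix the source TXT
#' file: (a) the table's final year must equal `last_year`; (b) every table
#' year must lie within the series span; (c) every missing ring (width 0)
#' must have zero ducts.
#'
#' @param table A `dated_duct_table`.
#' @param series The matching `ring_width_series`.
#' @param last_year Calendar year of the outermost measured ring.
#' @return An object of class `alignment_report` with a character vector
#'   `violations` (empty when consistent).
#' @export
verify_alignment <- function(table, series, last_year) {
  stopifnot(inherits(table, "dated_duct_table"),
            inherits(series, "ring_width_series"))
  last_year <- as.integer(last_year)
  violations <- character(0)

  expected_rings <- last_year - table$first_year + 1L
  found <- length(table$ducts)
  if (max(table$years) != last_year) {
    violations <- c(violations, sprintf(
      "year count mismatch: expected %d rings (%d-%d), found %d",
      expected_rings, table$first_year, last_year, found))
  }
  span_first <- series$first_year
  span_last <- series_last_year(series)
  outside <- table$years[table$years < span_first | table$years > span_last]
  for (y in outside) {
    violations <- c(violations, sprintf(
      "year %d outside ring-width series span %d-%d", y, span_first, span_last))
  }
  inside <- table$years >= span_first & table$years <= span_last
  for (i in which(inside)) {
    y <- table$years[i]
    w <- series$widths[y - span_first + 1L]
    if (w == 0 && length(table$ducts[[i]]) > 0L) {
      violations <- c(violations, sprintf(
        "duct recorded in missing ring %d", y))
    }
  }
  structure(list(sample_id = table$sample_id, violations = violations),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  if (length(x$violations) == 0L) {
    cat(sprintf("<alignment_report> %s: consistent\n", x$sample_id))
  } else {
    cat(sprintf("<alignment_report> %s: %d violation(s)\n",
                x$sample_id, length(x$violations)))
    for (v in x$violations) cat("  - ", v, "\n", sep = "")
  }
  invisible(x)
}

#' Write a dated duct table as a per-core CSV
#'
#' One row per duct (`sample_id,year,duct_area_mm2`); a year with no ducts
#' is kept as a single row with an empty area, so the full ring sequence
#' survives the round trip.
#'
#' @param table A `dated_duct_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dated_ducts <- function(table, path) {
  stopifnot(inherits(table, "dated_duct_table"))
  n <- pmax(lengths(table$ducts), 1L)
  year <- rep(table$years, n)
  area <- unlist(lapply(table$ducts, function(a) if (length(a)) a else NA_real_),
                 use.names = FALSE)
  df <- data.frame(sample_id = table$sample_id, year = year,
                   duct_area_mm2 = area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-core dated duct CSV back into a table
#'
#' Inverse of [write_dated_ducts()]. The file must cover a contiguous year
#' sequence (empty years present as blank-area rows).
#'
#' @param path CSV path with columns `sample_id`, `year`, `duct_area_mm2`.
#' @return A `dated_duct_table`.
#' @export
read_dated_ducts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "year", "duct_area_mm2")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("%s: no rows", path), call. = FALSE)
  ids <- unique(df$sample_id)
  if (length(ids) != 1L) {
    stop(sprintf("%s: multiple sample_ids in one per-core file", path),
         call. = FALSE)
  }
  years <- sort(unique(df$year))
  if (!identical(as.integer(years), seq(min(years), max(years)))) {
    stop(sprintf("%s: years are not contiguous", path), call. = FALSE)
  }
  ducts <- lapply(years, function(y) {
    a <- df$duct_area_mm2[df$year == y]
    a <- a[!is.na(a)]
    a
  })
  dated_duct_table(ids, min(years), ducts)
}
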