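# Tucson (decadal) RWL ring-width file support.
#
# Layout: columns 1-8 hold the series ID, then a decade year, then up to ten
# integer widths (one per year). The terminal stop marker doubles as the
# precision flag: 999 means the integers are hundredths of a millimetre,
# -9999 means thousandths.

#' Construct a ring-width series
#'
#' A dated, contiguous sequence of annual ring widths for one core. Width 0
#' is legal and denotes a locally absent (missing) ring.
#'
#' @param sample_id Series identifier, non-empty, at most 8 characters
#'   (Tucson limit).
#' @param first_year Calendar year of the first width.
#' @param widths Numeric vector of ring widths in mm, one per consecutive
#'   year; all values must be >= 0.
#' @param precision Measurement precision in mm: `0.01` or `0.001`.
#' @return An object of class `ring_width_series`.
#' @export
ring_width_series <- function(sample_id, first_year, widths, precision = 0.01) {
  if (!is.character(sample_id) || length(sample_id) != 1L ||
      is.na(sample_id) || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  if (nchar(sample_id) > 8L) {
    stop(sprintf("sample_id '%s' exceeds the Tucson 8-character limit",
                 sample_id), call. = FALSE)
  }
  first_year <- as.integer(first_year)
  if (length(first_year) != 1L || is.na(first_year)) {
    stop("first_year must be a single integer year", call. = FALSE)
  }
  widths <- as.numeric(widths)
  if (length(widths) == 0L) stop("widths must be non-empty", call. = FALSE)
  if (anyNA(widths) || any(widths < 0)) {
    stop("widths must be non-negative and non-missing (0 marks a missing ring)",
         call. = FALSE)
  }
  precision <- match_precision(precision)
  structure(
    list(sample_id = sample_id, first_year = first_year,
         widths = widths, precision = precision),
    class = "ring_width_series"
  )
}

match_precision <- function(precision) {
  precision <- as.numeric(precision)
  if (length(precision) != 1L || is.na(precision) ||
      !any(abs(precision - c(0.01, 0.001)) < 1e-12)) {
    stop("precision must be 0.01 or 0.001 (mm)", call. = FALSE)
  }
  if (abs(precision - 0.01) < 1e-12) 0.01 else 0.001
}

#' Last dated year of a ring-width series
#' @param series A `ring_width_series`.
#' @return Integer calendar year of the final ring.
#' @export
series_last_year <- function(series) {
  stopifnot(inherits(series, "ring_width_series"))
  series$first_year + length(series$widths) - 1L
}

#' @export
print.ring_width_series <- function(x, ...) {
  cat(sprintf("<ring_width_series> %s: %d rings, %d-%d, precision %g mm\n",
              x$sample_id, length(x$widths), x$first_year,
              series_last_year(x), x$precision))
  invisible(x)
}

#' Construct a collection of ring-width series
#'
#' @param series A list of `ring_width_series` objects with unique sample IDs.
#' @return An object of class `rwl_collection`: a list of series named by
#'   sample ID.
#' @export
rwl_collection <- function(series = list()) {
  if (!is.list(series)) stop("series must be a list", call. = FALSE)
  ok <- vapply(series, inherits, logical(1), what = "ring_width_series")
  if (length(series) && !all(ok)) {
    stop("all elements must be ring_width_series objects", call. = FALSE)
  }
  ids <- vapply(series, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(series) <- ids
  structure(list(series = series), class = "rwl_collection")
}

#' @export
print.rwl_collection <- function(x, ...) {
  cat(sprintf("<rwl_collection> %d series: %s\n", length(x$series),
              paste(names(x$series), collapse = ", ")))
  invisible(x)
}

#' @export
length.rwl_collection <- function(x) length(x$series)

# round half up at a given precision, tolerant of binary representation of
# decimal inputs (1.005/0.01 is stored fractionally below 100.5)
round_half_up_units <- function(x, precision) {
  r <- x / precision
  floor(r + 0.5 + 1e-9 * pmax(1, abs(r)))
}

#' Read a Tucson-format RWL file
#'
#' Parses all series in a decadal-layout ring-width file. The measurement
#' precision of each series is detected from its terminal stop marker
#' (999 => hundredths of mm, -9999 => thousandths); the marker is stripped
#' and values are returned in mm. Up to three leading header lines that do
#' not match the numeric layout are skipped.
#'
#' @param path Path to an `.rwl` file.
#' @return An `rwl_collection`.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) return(rwl_collection())

  # a line is data-like when the ID field is non-empty and the first token
  # after it parses as an integer year; headers fail that, while a corrupt
  # value field on a data-like line is a parse error, not a header
  parse_line <- function(line) {
    id <- trimws(substr(line, 1L, 8L))
    rest <- substring(line, 9L)
    tokens <- strsplit(trimws(rest), "\\s+")[[1]]
    if (!nzchar(id) || length(tokens) < 2L) return("header")
    suppressWarnings(year <- as.numeric(tokens[1L]))
    if (is.na(year) || year != floor(year)) return("header")
    suppressWarnings(vals <- as.numeric(tokens[-1L]))
    if (anyNA(vals) || any(vals != floor(vals))) return("malformed")
    list(id = id, year = as.integer(year), values = vals)
  }

  # series records in file order: id -> list(first_year, raw integer values)
  order_ids <- character(0)
  acc <- list()
  skipped <- 0L
  for (i in seq_along(lines_keep)) {
    lineno <- lines_keep[i]
    rec <- parse_line(lines[lineno])
    if (identical(rec, "malformed")) {
      stop(sprintf("malformed RWL data at line %d of %s", lineno, path),
           call. = FALSE)
    }
    if (identical(rec, "header")) {
      if (i <= 3L && skipped == i - 1L) { skipped <- skipped + 1L; next }
      stop(sprintf("unparseable RWL line %d of %s (headers are only skipped in the first 3 lines)",
                   lineno, path), call. = FALSE)
    }
    key <- rec$id
    if (is.null(acc[[key]])) {
      acc[[key]] <- list(first_year = rec$year, values = rec$values,
                         decades = rec$year)
      order_ids <- c(order_ids, key)
    } else {
      if (rec$year %in% acc[[key]]$decades) {
        stop(sprintf("duplicate decade %d for series %s (line %d)",
                     rec$year, key, lineno), call. = FALSE)
      }
      if (rec$year < acc[[key]]$decades[length(acc[[key]]$decades)]) {
        stop(sprintf("out-of-order decade %d for series %s (line %d)",
                     rec$year, key, lineno), call. = FALSE)
      }
      # the decade field labels the line; widths are concatenated in file
      # order, so years are always contiguous from first_year
      acc[[key]]$values <- c(acc[[key]]$values, rec$values)
      acc[[key]]$decades <- c(acc[[key]]$decades, rec$year)
    }
  }

  series <- lapply(order_ids, function(id) {
    raw <- acc[[id]]$values
    n <- length(raw)
    if (raw[n] == -9999) {
      precision <- 0.001; raw <- raw[-n]
    } else if (raw[n] == 999) {
      precision <- 0.01; raw <- raw[-n]
    } else {
      warning(sprintf("series %s has no stop marker; assuming 0.01 mm precision",
                      id), call. = FALSE)
      precision <- 0.01
    }
    if (length(raw) == 0L) {
      stop(sprintf("series %s contains a stop marker but no widths", id),
           call. = FALSE)
    }
    if (any(raw < 0)) {
      stop(sprintf("negative width value in series %s", id), call. = FALSE)
    }
    ring_width_series(id, acc[[id]]$first_year, raw * precision, precision)
  })
  rwl_collection(series)
}

#' Write a Tucson-format RWL file
#'
#' Emits standard decadal layout with the stop marker matching `precision`.
#' Widths not representable at the requested precision are rounded half-up
#' with a warning. Reading the result back reproduces all widths exactly at
#' the stated precision.
#'
#' @param collection An `rwl_collection`.
#' @param path Output path.
#' @param precision Output precision in mm: `0.01` (stop marker 999) or
#'   `0.001` (stop marker -9999).
#' @return Invisibly, `path`.
#' @export
write_rwl <- function(collection, path, precision = 0.01) {
  stopifnot(inherits(collection, "rwl_collection"))
  precision <- match_precision(precision)
  stop_marker <- if (precision == 0.01) 999L else -9999L
  out <- character(0)
  for (series in collection$series) {
    if (nchar(series$sample_id) > 8L) {
      stop(sprintf("sample_id '%s' exceeds 8 characters; Tucson format cannot represent it",
                   series$sample_id), call. = FALSE)
    }
    units <- round_half_up_units(series$widths, precision)
    err <- abs(units * precision - series$widths)
    if (any(err > 1e-9)) {
      lost <- which(err > 1e-9)
      warning(sprintf(
        "series %s: %d width(s) rounded half-up to %g mm precision (first at year %d)",
        series$sample_id, length(lost), precision,
        series$first_year + lost[1L] - 1L), call. = FALSE)
    }
    vals <- c(as.integer(units), stop_marker)
    years <- seq(series$first_year, by = 1L, length.out = length(vals))
    decade <- (years %/% 10L) * 10L
    for (d in unique(decade)) {
      sel <- decade == d
      out <- c(out, paste0(
        sprintf("%-8s", series$sample_id),
        sprintf("%4d", years[sel][1L]),
        paste0(sprintf("%6d", vals[sel]), collapse = "")
      ))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract an inclusive year range from a ring-width series
#'
#' Duct years must be fully covered by the ring-width record, so requesting
#' years outside the series span is an error, not an NA fill.
#'
#' @param series A `ring_width_series`.
#' @param first,last Calendar year bounds, `first <= last`.
#' @return A data frame with columns `year` and `width_mm`.
#' @export
series_slice <- function(series, first, last) {
  stopifnot(inherits(series, "ring_width_series"))
  first <- as.integer(first); last <- as.integer(last)
  if (first > last) stop("first must be <= last", call. = FALSE)
  span_first <- series$first_year
  span_last <- series_last_year(series)
  wanted <- first:last
  missing <- wanted[wanted < span_first | wanted > span_last]
  if (length(missing)) {
    stop(sprintf(
      "series %s (%d-%d) does not cover requested year(s): %s",
      series$sample_id, span_first, span_last,
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- wanted - span_first + 1L
  data.frame(year = wanted, width_mm = series$widths[idx])
}
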