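# Independent oracles and random fixture builders, deliberately written
# with different mechanics than the package implementation.

# Brute-force sentinel splitter: locate sentinel positions first, then cut
# the stream by index arithmetic (the package uses a single accumulating
# pass instead).
oracle_split_sentinels <- function(areas, is_sentinel) {
  stops <- which(is_sentinel)
  lapply(seq_along(stops), function(k) {
    lo <- if (k == 1L) 0L else stops[k - 1L]
    hi <- stops[k] - 1L
    if (hi < lo + 1L) numeric(0) else areas[(lo + 1L):hi]
  })
}

# Minimal independent Tucson decoder: regex-token the whole file at once
# instead of per-line field extraction.
oracle_decode_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (line in lines) {
    id <- sub("\\s+$", "", substr(line, 1, 8))
    body <- substring(line, 9)
    nums <- as.numeric(regmatches(body, gregexpr("-?[0-9]+", body))[[1]])
    if (is.null(out[[id]])) {
      out[[id]] <- list(first_year = nums[1], raw = nums[-1])
    } else {
      out[[id]]$raw <- c(out[[id]]$raw, nums[-1])
    }
  }
  lapply(out, function(s) {
    n <- length(s$raw)
    scale <- if (s$raw[n] == -9999) 0.001 else if (s$raw[n] == 999) 0.01 else NA
    list(first_year = s$first_year, widths = s$raw[-n] * scale,
         precision = scale)
  })
}

# Random sentinel-delimited measurement stream with known group structure.
random_sentinel_stream <- function(n, p_duct = 0.6) {
  raw <- ifelse(stats::runif(n) < p_duct,
                stats::runif(n, 1e-4, 1e-2), 0)
  raw[n] <- 0  # terminal sentinel required
  raw
}

# Random valid RWL collection with widths exactly representable at the
# requested precision.
random_rwl_collection <- function(n_series = 3L, precision = 0.01) {
  series <- lapply(seq_len(n_series), function(k) {
    n <- sample(3:40, 1)
    units <- sample(0:400, n, replace = TRUE)  # includes 0 = missing ring
    ring_width_series(sprintf("RND%02d%s", k, sample(letters, 1)),
                      sample(1700:1990, 1), units * precision, precision)
  })
  rwl_collection(series)
}

# Measurement-file text fixture on disk.
write_imagej_txt <- function(path, areas_in2, sep = "\t", label = "core.tif") {
  header <- paste(" ", "Label", "Area", sep = sep)
  rows <- paste(seq_along(areas_in2), label,
                formatC(areas_in2, format = "g", digits = 12), sep = sep)
  writeLines(c(header, rows), path)
  path
}
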