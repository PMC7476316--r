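# End-to-end chronology assembly, quality control and plotting.

#' Build a master resin-duct chronology
#'
#' Batch-ingests per-core dated-duct CSVs, enforces the sample-ID naming
#' contract against the RWL ring-width file (every CSV filename stem must
#' match a series ID exactly, case-sensitively), computes unstandardized
#' and standardized metrics per core, optionally combines replicate cores
#' per tree, and returns the master table sorted by sample ID then year.
#'
#' Years outside `[first_year, last_year]` in any core are an error rather
#' than being trimmed: they indicate a misalignment to fix at source.
#'
#' @param duct_dir Directory of per-core CSVs written by
#'   [write_dated_ducts()] (`<sampleID>.csv`).
#' @param rwl_path Path to the site RWL ring-width file.
#' @param geometry A `core_geometry`.
#' @param first_year,last_year Inclusive calendar-year bounds of the
#'   measured record.
#' @param combine If `TRUE`, sum replicate cores per tree (core letter =
#'   final character of the sample ID) before assembling the master table.
#' @param log_path Optional path for a plain-text run log (inputs,
#'   parameters, warnings).
#' @return An object of class `master_chronology` with fields `rows` (data
#'   frame) and `metadata`.
#' @export
build_master <- function(duct_dir, rwl_path, geometry, first_year, last_year,
                         combine = FALSE, log_path = NULL) {
  stopifnot(inherits(geometry, "core_geometry"))
  first_year <- as.integer(first_year); last_year <- as.integer(last_year)
  if (first_year > last_year) {
    stop("first_year must be <= last_year", call. = FALSE)
  }
  files <- sort(list.files(duct_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no per-core CSV files in %s", duct_dir), call. = FALSE)
  }
  stems <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(stems)) {
    stop(sprintf("duplicate core files for sample_id: %s",
                 paste(unique(stems[duplicated(stems)]), collapse = ", ")),
         call. = FALSE)
  }
  collection <- read_rwl(rwl_path)
  unmatched <- setdiff(stems, names(collection$series))
  if (length(unmatched)) {
    stop(sprintf(
      "sample_id(s) with no matching RWL series: %s (available series: %s)",
      paste(unmatched, collapse = ", "),
      paste(names(collection$series), collapse = ", ")), call. = FALSE)
  }

  warnings_seen <- character(0)
  per_core <- withCallingHandlers(
    lapply(seq_along(files), function(i) {
      table <- read_dated_ducts(files[i])
      if (!identical(table$sample_id, stems[i])) {
        stop(sprintf("%s: sample_id column '%s' does not match filename stem",
                     files[i], table$sample_id), call. = FALSE)
      }
      out_of_range <- table$years[table$years < first_year |
                                  table$years > last_year]
      if (length(out_of_range)) {
        stop(sprintf(
          "core %s has year(s) outside %d-%d: %s; fix the source file",
          table$sample_id, first_year, last_year,
          paste(range(out_of_range), collapse = "-")), call. = FALSE)
      }
      rows <- unstandardized_metrics(table)
      standardized_metrics(rows, collection$series[[table$sample_id]], geometry)
    }),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  if (combine) {
    prefixes <- substr(stems, 1L, nchar(stems) - 1L)
    groups <- split(per_core, prefixes)
    rows <- do.call(rbind, lapply(groups, combine_cores, geometry = geometry))
  } else {
    rows <- do.call(rbind, per_core)
  }
  rows <- rows[order(rows$sample_id, rows$year), , drop = FALSE]
  rownames(rows) <- NULL

  chron <- structure(
    list(rows = rows,
         metadata = list(core_width = geometry$core_width,
                         first_year = first_year, last_year = last_year,
                         combine = combine,
                         n_cores = length(files),
                         rwl_path = rwl_path, duct_dir = duct_dir)),
    class = "master_chronology")

  if (!is.null(log_path)) {
    log <- c(
      sprintf("ductchron build log - %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("duct_dir: %s", duct_dir),
      sprintf("rwl: %s", rwl_path),
      sprintf("core_width_mm: %g", geometry$core_width),
      sprintf("years: %d-%d", first_year, last_year),
      sprintf("combine: %s", combine),
      sprintf("cores: %s", paste(stems, collapse = ", ")),
      sprintf("rows: %d", nrow(rows)),
      if (length(warnings_seen)) paste("warning:", warnings_seen) else "warnings: none"
    )
    writeLines(log, log_path)
  }
  for (w in warnings_seen) warning(w, call. = FALSE)
  chron
}

#' @export
print.master_chronology <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<master_chronology> %d rows, %d series, years %d-%d, core width %g mm%s\n",
    nrow(x$rows), length(unique(x$rows$sample_id)),
    m$first_year, m$last_year, m$core_width,
    if (isTRUE(m$combine)) " (tree-level)" else ""))
  invisible(x)
}

#' Write a master chronology CSV
#'
#' Column order: sample_id, year, duct_size_mm2, duct_production,
#' total_duct_area_mm2, duct_density_per_mm2, relative_duct_area_pct,
#' ring_width_mm, ring_area_mm2. Values are rounded to 6 significant
#' digits at write time only; identical inputs yield a byte-identical file.
#'
#' @param chron A `master_chronology`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_master <- function(chron, path) {
  stopifnot(inherits(chron, "master_chronology"))
  rows <- chron$rows[, c("sample_id", "year", metric_columns)]
  for (col in metric_columns) {
    if (col != "duct_production") rows[[col]] <- signif(rows[[col]], 6)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a master chronology CSV
#'
#' @param path CSV written by [write_master()].
#' @param metadata Optional metadata list to attach.
#' @return A `master_chronology`.
#' @export
read_master <- function(path, metadata = list()) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "year", metric_columns)
  if (!all(need %in% names(rows))) {
    stop(sprintf("%s: expected master chronology columns %s", path,
                 paste(setdiff(need, names(rows)), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(metadata$first_year) && nrow(rows)) {
    metadata$first_year <- min(rows$year)
    metadata$last_year <- max(rows$year)
  }
  if (is.null(metadata$core_width) && nrow(rows)) {
    w <- rows$ring_width_mm > 0
    metadata$core_width <- if (any(w)) {
      stats::median(rows$ring_area_mm2[w] / rows$ring_width_mm[w])
    } else NA_real_
  }
  structure(list(rows = rows, metadata = metadata),
            class = "master_chronology")
}

#' Default plausibility rules for quality control
#'
#' @param size_min,size_max Plausible band for mean duct size (mm^2).
#' @return A named list of QC thresholds.
#' @export
qc_rules <- function(size_min = 0.001, size_max = 0.5) {
  list(size_min = size_min, size_max = size_max)
}

#' Screen a chronology for implausible values
#'
#' Pure-predicate rules: duct size outside the plausible band; relative
#' duct area above 100% of the ring; any negative metric; missing rings
#' (NA density) listed for review. Also returns per-core min/mean/max
#' summaries of each metric.
#'
#' @param chron A `master_chronology`.
#' @param rules Thresholds from [qc_rules()].
#' @return An object of class `qc_report` with data frames `flags`
#'   (`sample_id`, `year`, `field`, `value`, `rule`), `missing_rings`, and
#'   `summary`.
#' @export
qc_checks <- function(chron, rules = qc_rules()) {
  stopifnot(inherits(chron, "master_chronology"))
  rows <- chron$rows
  flags <- data.frame(sample_id = character(0), year = integer(0),
                      field = character(0), value = numeric(0),
                      rule = character(0))
  add_flag <- function(sel, field, rule) {
    sel <- which(sel)
    if (length(sel)) {
      flags <<- rbind(flags, data.frame(
        sample_id = rows$sample_id[sel], year = rows$year[sel],
        field = field, value = rows[[field]][sel], rule = rule))
    }
  }
  size <- rows$duct_size_mm2
  add_flag(!is.na(size) & (size < rules$size_min | size > rules$size_max),
           "duct_size_mm2",
           sprintf("duct size outside plausible band %g-%g mm^2",
                   rules$size_min, rules$size_max))
  rel <- rows$relative_duct_area_pct
  add_flag(!is.na(rel) & rel > 100,
           "relative_duct_area_pct", "relative area exceeds 100%")
  for (col in metric_columns) {
    v <- rows[[col]]
    add_flag(!is.na(v) & v < 0, col, "negative value")
  }
  missing_rings <- rows[is.na(rows$duct_density_per_mm2) &
                        rows$ring_area_mm2 == 0,
                        c("sample_id", "year"), drop = FALSE]
  rownames(missing_rings) <- NULL

  summarise_core <- function(d) {
    out <- lapply(metric_columns, function(col) {
      v <- d[[col]][!is.na(d[[col]])]
      if (!length(v)) c(min = NA_real_, mean = NA_real_, max = NA_real_)
      else c(min = min(v), mean = mean(v), max = max(v))
    })
    names(out) <- metric_columns
    out
  }
  summary <- lapply(split(rows, rows$sample_id), summarise_core)

  structure(list(flags = flags, missing_rings = missing_rings,
                 summary = summary),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d flag(s), %d missing ring(s), %d core(s)\n",
              nrow(x$flags), nrow(x$missing_rings), length(x$summary)))
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}

#' Plot one metric of a chronology per core
#'
#' Line plot over calendar years, one line per core, NA values (missing
#' rings) shown as gaps. Writes a PNG.
#'
#' @param chron A `master_chronology`.
#' @param metric One of the seven numeric metric columns.
#' @param out Output PNG path.
#' @param width,height,res Device parameters passed to [grDevices::png()].
#' @return Invisibly, `out`.
#' @export
plot_chronology <- function(chron, metric, out,
                            width = 1200, height = 600, res = 120) {
  stopifnot(inherits(chron, "master_chronology"))
  if (!metric %in% metric_columns) {
    stop(sprintf("unknown metric '%s'; valid fields: %s",
                 metric, paste(metric_columns, collapse = ", ")),
         call. = FALSE)
  }
  rows <- chron$rows
  if (nrow(rows) == 0L) stop("nothing to plot: chronology is empty",
                             call. = FALSE)
  ids <- sort(unique(rows$sample_id))
  cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")[seq_along(ids)]
  grDevices::png(out, width = width, height = height, res = res)
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- range(rows[[metric]], na.rm = TRUE)
  if (!all(is.finite(ylim))) ylim <- c(0, 1)
  plot(NA, xlim = range(rows$year), ylim = ylim,
       xlab = "year", ylab = metric, main = "resin duct chronology")
  for (k in seq_along(ids)) {
    d <- rows[rows$sample_id == ids[k], ]
    graphics::lines(d$year, d[[metric]], col = cols[k])
    graphics::points(d$year, d[[metric]], col = cols[k], pch = 16, cex = 0.4)
  }
  graphics::legend("topright", legend = ids, col = cols, lty = 1, cex = 0.7,
                   bty = "n")
  invisible(out)
}
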