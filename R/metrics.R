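# Per-ring resin duct defense metrics.
#
# Three unstandardized metrics: duct size (mean area per ring, mm^2), duct
# production (count per ring), total duct area (sum per ring, mm^2). Two
# standardized metrics adjust for growth rate by dividing by ring area
# (ring width x core diameter): duct density (count mm^-2 yr^-1) and
# relative duct area (% of the annual ring).

#' Core geometry
#'
#' @param core_width Average width (diameter) of the increment core in mm,
#'   e.g. 5.15 for a standard borer. Constant along the core; per-ring core
#'   widths are out of scope.
#' @return An object of class `core_geometry`.
#' @export
core_geometry <- function(core_width) {
  core_width <- as.numeric(core_width)
  if (length(core_width) != 1L || is.na(core_width) || core_width <= 0) {
    stop("core_width must be a single positive number (mm)", call. = FALSE)
  }
  structure(list(core_width = core_width), class = "core_geometry")
}

metric_columns <- c("duct_size_mm2", "duct_production", "total_duct_area_mm2",
                    "duct_density_per_mm2", "relative_duct_area_pct",
                    "ring_width_mm", "ring_area_mm2")

#' Unstandardized duct metrics for one core
#'
#' Per ring: duct size = mean of that year's duct areas (NA when the ring
#' has no ducts), duct production = count, total duct area = sum.
#'
#' @param table A `dated_duct_table`.
#' @return A data frame with columns `sample_id`, `year`, `duct_size_mm2`,
#'   `duct_production`, `total_duct_area_mm2`.
#' @export
unstandardized_metrics <- function(table) {
  stopifnot(inherits(table, "dated_duct_table"))
  production <- lengths(table$ducts)
  total <- vapply(table$ducts, sum, numeric(1))
  size <- ifelse(production > 0, total / production, NA_real_)
  data.frame(
    sample_id = table$sample_id,
    year = table$years,
    duct_size_mm2 = size,
    duct_production = as.integer(production),
    total_duct_area_mm2 = total
  )
}

#' Add growth-standardized duct metrics from ring widths
#'
#' Ring area = ring width x core width. Duct density = production / ring
#' area; relative duct area = 100 x total duct area / ring area. A missing
#' ring (width 0) has zero ring area, so both standardized metrics are NA
#' there; production and total are retained.
#'
#' @param rows Output of [unstandardized_metrics()].
#' @param series The matching `ring_width_series`; every row's year must be
#'   covered by it.
#' @param geometry A `core_geometry`.
#' @return The input data frame extended with `duct_density_per_mm2`,
#'   `relative_duct_area_pct`, `ring_width_mm`, `ring_area_mm2`.
#' @export
standardized_metrics <- function(rows, series, geometry) {
  stopifnot(is.data.frame(rows), inherits(series, "ring_width_series"),
            inherits(geometry, "core_geometry"))
  if (nrow(rows) == 0L) stop("no metric rows to standardize", call. = FALSE)
  sl <- series_slice(series, min(rows$year), max(rows$year))
  width <- sl$width_mm[match(rows$year, sl$year)]
  ring_area <- width * geometry$core_width
  density <- ifelse(ring_area > 0, rows$duct_production / ring_area, NA_real_)
  relative <- ifelse(ring_area > 0,
                     100 * rows$total_duct_area_mm2 / ring_area, NA_real_)
  rows$duct_density_per_mm2 <- density
  rows$relative_duct_area_pct <- relative
  rows$ring_width_mm <- width
  rows$ring_area_mm2 <- ring_area
  rows
}

#' Estimate the duct initiation rate per unit ring area
#'
#' Regresses duct production on ring area through the origin with
#' inverse-ring-area weights. Under the Poisson picture (duct counts with
#' mean proportional to sampled ring area) the count variance also scales
#' with ring area, so these weights are the inverse-variance choice: the
#' estimate reduces to total ducts / total ring area and its standard
#' error has the right sampling scale. Missing rings (zero area) carry no
#' information about the rate and are excluded.
#'
#' @param rows A metrics data frame with `duct_production` and
#'   `ring_area_mm2` columns (per-core or tree-level).
#' @return A list with `estimate` (ducts per mm^2), `se`, and `n_rings`.
#' @export
estimate_duct_rate <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("duct_production", "ring_area_mm2") %in% names(rows)))
  d <- rows[!is.na(rows$ring_area_mm2) & rows$ring_area_mm2 > 0, ]
  if (nrow(d) < 2L) {
    stop("need at least 2 rings with positive ring area", call. = FALSE)
  }
  fit <- stats::lm(duct_production ~ 0 + ring_area_mm2, data = d,
                   weights = 1 / d$ring_area_mm2)
  list(estimate = unname(stats::coef(fit)[1L]),
       se = sqrt(stats::vcov(fit)[1L, 1L]),
       n_rings = nrow(d))
}

#' Combine replicate cores of one tree
#'
#' Sums duct production, total duct area and ring area across the cores of
#' a tree for each year with data in any core, then recomputes duct size,
#' density and relative area from the combined sums (so the
#' size x production = total identity holds exactly at tree level). The
#' core letter is assumed to be the final character of the sample ID; the
#' combined rows carry the common prefix as tree ID.
#'
#' @param rows_by_core List of per-core metric data frames (full rows, as
#'   returned by [standardized_metrics()]).
#' @param geometry A `core_geometry` (used to express combined ring area as
#'   an equivalent summed ring width).
#' @return A tree-level metrics data frame with the same columns.
#' @export
combine_cores <- function(rows_by_core, geometry) {
  stopifnot(is.list(rows_by_core), length(rows_by_core) >= 1L,
            inherits(geometry, "core_geometry"))
  ids <- vapply(rows_by_core, function(r) r$sample_id[1L], character(1))
  prefixes <- substr(ids, 1L, nchar(ids) - 1L)
  if (length(unique(prefixes)) != 1L) {
    stop(sprintf(
      "cores do not share a tree ID prefix after dropping the core letter: %s",
      paste(ids, collapse = ", ")), call. = FALSE)
  }
  tree_id <- prefixes[1L]
  all_rows <- do.call(rbind, rows_by_core)
  years <- sort(unique(all_rows$year))
  agg <- function(col) {
    vapply(years, function(y) sum(all_rows[[col]][all_rows$year == y]),
           numeric(1))
  }
  production <- agg("duct_production")
  total <- agg("total_duct_area_mm2")
  ring_area <- agg("ring_area_mm2")
  size <- ifelse(production > 0, total / production, NA_real_)
  density <- ifelse(ring_area > 0, production / ring_area, NA_real_)
  relative <- ifelse(ring_area > 0, 100 * total / ring_area, NA_real_)
  data.frame(
    sample_id = tree_id,
    year = years,
    duct_size_mm2 = size,
    duct_production = as.integer(production),
    total_duct_area_mm2 = total,
    duct_density_per_mm2 = density,
    relative_duct_area_pct = relative,
    ring_width_mm = ring_area / geometry$core_width,
    ring_area_mm2 = ring_area
  )
}
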