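# Synthetic cores with known ground truth.
#
# The generator emulates the data a real study produces: a ring-width
# series with a negative-exponential age trend plus AR(1) noise and
# occasional missing rings, duct counts Poisson in ring area at a rate
# lambda (ducts per mm^2), and lognormal duct sizes truncated above a
# floor so no synthetic duct can round down into a sentinel zero.

#' Default parameters for the synthetic core generator
#'
#' Defaults describe a 5.15 mm increment core with rings around 1-2 mm,
#' a duct rate of 0.2 ducts per mm^2 of ring area (mean duct size
#' ~0.05 mm^2), and a 2% missing-ring rate; roughly 13% of years carry no
#' ducts, the regime that motivates taking two cores per tree.
#'
#' @param sample_id Sample ID for the core (<= 8 characters).
#' @param first_year Calendar year of the innermost ring.
#' @param n_years Number of rings to simulate.
#' @param width_init Initial (juvenile) ring width, mm.
#' @param width_decay Negative-exponential age-trend rate per year.
#' @param ar_coef AR(1) coefficient of the width noise, in (-1, 1).
#' @param noise_sd Innovation standard deviation of the width noise, mm.
#' @param duct_rate Expected ducts per mm^2 of ring area (lambda).
#' @param size_meanlog,size_sdlog Lognormal parameters of duct area (mm^2).
#' @param size_floor Truncation floor for duct area, mm^2.
#' @param missing_prob Probability a ring is locally absent (width 0).
#' @param core_width Core diameter in mm.
#' @return A named list of generator parameters.
#' @export
core_sim_params <- function(sample_id = "SYN001a", first_year = 1900L,
                            n_years = 100L,
                            width_init = 2.0, width_decay = 0.01,
                            ar_coef = 0.5, noise_sd = 0.2,
                            duct_rate = 0.2,
                            size_meanlog = log(0.05), size_sdlog = 0.4,
                            size_floor = 0.005,
                            missing_prob = 0.02, core_width = 5.15) {
  p <- list(sample_id = sample_id, first_year = as.integer(first_year),
            n_years = as.integer(n_years),
            width_init = width_init, width_decay = width_decay,
            ar_coef = ar_coef, noise_sd = noise_sd,
            duct_rate = duct_rate,
            size_meanlog = size_meanlog, size_sdlog = size_sdlog,
            size_floor = size_floor,
            missing_prob = missing_prob, core_width = core_width)
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$n_years < 1L) stop("n_years must be >= 1", call. = FALSE)
  if (p$width_init <= 0 || p$width_decay < 0) {
    stop("width_init must be positive and width_decay non-negative",
         call. = FALSE)
  }
  if (abs(p$ar_coef) >= 1) stop("ar_coef must lie in (-1, 1)", call. = FALSE)
  if (p$noise_sd < 0 || p$duct_rate < 0 || p$size_sdlog < 0) {
    stop("noise_sd, duct_rate and size_sdlog must be non-negative",
         call. = FALSE)
  }
  if (p$size_floor <= 0) stop("size_floor must be positive", call. = FALSE)
  if (p$missing_prob < 0 || p$missing_prob >= 1) {
    stop("missing_prob must be in [0, 1)", call. = FALSE)
  }
  if (p$core_width <= 0) stop("core_width must be positive", call. = FALSE)
  if (nchar(p$sample_id) > 8L) {
    stop("sample_id exceeds 8 characters", call. = FALSE)
  }
  invisible(p)
}

#' Simulate one core with known ground truth
#'
#' Ring widths follow `max(0, width_init * exp(-decay * t) + AR(1) noise)`;
#' a ring is forced to width 0 (and zero ducts) with probability
#' `missing_prob`. Duct counts are Poisson with mean
#' `duct_rate * ring_area`; duct areas are lognormal truncated below at
#' `size_floor`. Fully reproducible under `seed`.
#'
#' @param params Parameter list from [core_sim_params()].
#' @param seed Integer RNG seed.
#' @return An object of class `core_truth`: the parameters plus
#'   `ring_widths_mm` and `ducts_per_year` (list of area vectors, mm^2).
#' @export
simulate_core <- function(params = core_sim_params(), seed = 1L) {
  validate_sim_params(params)
  set.seed(as.integer(seed))
  n <- params$n_years
  t <- seq_len(n) - 1L
  trend <- params$width_init * exp(-params$width_decay * t)
  noise <- numeric(n)
  innov <- stats::rnorm(n, sd = params$noise_sd)
  for (i in seq_len(n)) {
    noise[i] <- innov[i] + if (i > 1L) params$ar_coef * noise[i - 1L] else 0
  }
  widths <- pmax(0, trend + noise)
  missing <- stats::runif(n) < params$missing_prob
  widths[missing] <- 0

  ring_area <- widths * params$core_width
  counts <- stats::rpois(n, lambda = params$duct_rate * ring_area)
  counts[widths == 0] <- 0L
  ducts <- lapply(counts, function(k) {
    if (k == 0L) return(numeric(0))
    a <- stats::rlnorm(k, meanlog = params$size_meanlog,
                       sdlog = params$size_sdlog)
    pmax(a, params$size_floor)
  })
  structure(
    list(params = params, seed = as.integer(seed),
         sample_id = params$sample_id,
         first_year = params$first_year,
         ring_widths_mm = widths,
         ducts_per_year = ducts),
    class = "core_truth")
}

#' @export
print.core_truth <- function(x, ...) {
  cat(sprintf(
    "<core_truth> %s: %d rings from %d, %d ducts, %d missing ring(s), seed %d\n",
    x$sample_id, length(x$ring_widths_mm), x$first_year,
    sum(lengths(x$ducts_per_year)), sum(x$ring_widths_mm == 0), x$seed))
  invisible(x)
}

#' Ground-truth dated duct table of a simulated core
#'
#' @param truth A `core_truth`.
#' @return The `dated_duct_table` the pipeline should recover (before TXT
#'   rounding).
#' @export
truth_duct_table <- function(truth) {
  stopifnot(inherits(truth, "core_truth"))
  dated_duct_table(truth$sample_id, truth$first_year, truth$ducts_per_year)
}

#' Ground-truth ring-width series of a simulated core
#'
#' @param truth A `core_truth`.
#' @param precision RWL precision in mm.
#' @return A `ring_width_series` with widths quantized to `precision`, as
#'   an RWL file stores them.
#' @export
truth_ring_series <- function(truth, precision = 0.01) {
  stopifnot(inherits(truth, "core_truth"))
  precision <- match_precision(precision)
  q <- round_half_up_units(truth$ring_widths_mm, precision) * precision
  ring_width_series(truth$sample_id, truth$first_year, q, precision)
}

#' Write ImageJ-style TXT and RWL fixture files for a simulated core
#'
#' The TXT encodes each year's duct areas (converted to square inches and
#' written with 6 decimal places, emulating an ImageJ export) followed by
#' one sentinel zero; a missing or ductless ring contributes a bare
#' sentinel. The RWL encodes the quantized ring widths. Running the full
#' pipeline on the emitted pair recovers the truth (areas up to TXT
#' rounding).
#'
#' @param truth A `core_truth`.
#' @param out_dir Output directory (created if needed).
#' @param precision RWL precision in mm.
#' @param txt_digits Decimal places for TXT areas in square inches.
#' @return Named list with elements `txt`, `rwl` and `truth_json` (paths).
#' @export
emit_fixture_files <- function(truth, out_dir, precision = 0.01,
                               txt_digits = 6L) {
  stopifnot(inherits(truth, "core_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  txt_path <- file.path(out_dir, paste0(truth$sample_id, ".txt"))
  rwl_path <- file.path(out_dir, paste0(truth$sample_id, ".rwl"))
  json_path <- file.path(out_dir, paste0(truth$sample_id, "_truth.json"))

  areas_in2 <- unlist(lapply(truth$ducts_per_year, function(a) {
    c(round(a / IN2_TO_MM2, txt_digits), 0)
  }), use.names = FALSE)
  lines <- c(
    paste(" ", "Label", "Area", sep = "\t"),
    paste(seq_along(areas_in2),
          paste0(truth$sample_id, ".tif"),
          formatC(areas_in2, format = "f", digits = txt_digits),
          sep = "\t")
  )
  writeLines(lines, txt_path)

  series <- truth_ring_series(truth, precision)
  write_rwl(rwl_collection(list(series)), rwl_path, precision)

  jsonlite::write_json(
    list(sample_id = truth$sample_id, first_year = truth$first_year,
         seed = truth$seed, params = truth$params,
         ring_widths_mm = truth$ring_widths_mm,
         ducts_per_year = truth$ducts_per_year),
    json_path, auto_unbox = TRUE, digits = NA)
  list(txt = txt_path, rwl = rwl_path, truth_json = json_path)
}

#' Simulate a set of cores and emit their fixture files
#'
#' Cores are named `SYN<k><letter>` (letter cycling a, b) so replicate
#' combination can be exercised. All series are also merged into one site
#' RWL file.
#'
#' @param n_cores Number of cores.
#' @param n_years Rings per core.
#' @param seed Base RNG seed; core k uses `seed + k - 1`.
#' @param out_dir Output directory.
#' @param cores_per_tree Replicate cores per tree (1 or 2).
#' @param params Base parameters from [core_sim_params()]; sample_id,
#'   first_year and n_years are overridden per core.
#' @param precision RWL precision in mm.
#' @return List with `truths` (list of `core_truth`), `site_rwl` (path),
#'   and `files` (per-core emitted paths).
#' @export
simulate_cores <- function(n_cores = 2L, n_years = 100L, seed = 1L,
                           out_dir = tempfile("fixtures"),
                           cores_per_tree = 2L,
                           params = core_sim_params(),
                           precision = 0.01) {
  stopifnot(n_cores >= 1L, cores_per_tree %in% c(1L, 2L))
  letters_cycle <- letters[seq_len(cores_per_tree)]
  truths <- vector("list", n_cores)
  files <- vector("list", n_cores)
  for (k in seq_len(n_cores)) {
    tree <- (k - 1L) %/% cores_per_tree + 1L
    letter <- letters_cycle[(k - 1L) %% cores_per_tree + 1L]
    p <- params
    p$sample_id <- sprintf("SYN%03d%s", tree, letter)
    p$n_years <- as.integer(n_years)
    truths[[k]] <- simulate_core(p, seed = as.integer(seed) + k - 1L)
    files[[k]] <- emit_fixture_files(truths[[k]], out_dir,
                                     precision = precision)
  }
  site <- rwl_collection(lapply(truths, truth_ring_series,
                                precision = precision))
  site_rwl <- file.path(out_dir, "site.rwl")
  write_rwl(site, site_rwl, precision)
  list(truths = truths, site_rwl = site_rwl, files = files,
       out_dir = out_dir)
}
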