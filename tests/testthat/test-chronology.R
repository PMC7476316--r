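# builds a ready-to-compile directory: per-core dated-duct CSVs + site RWL
make_study <- function(dir, seed = 1L, n_cores = 2L, n_years = 30L) {
  sim <- simulate_cores(n_cores = n_cores, n_years = n_years, seed = seed,
                        out_dir = file.path(dir, "fixtures"))
  duct_dir <- file.path(dir, "ducts")
  dir.create(duct_dir, showWarnings = FALSE)
  for (f in sim$files) {
    mf <- read_measurements(f$txt)
    tab <- assign_years(mf, sim$truths[[1]]$first_year)
    write_dated_ducts(tab, file.path(duct_dir, paste0(tab$sample_id, ".csv")))
  }
  list(sim = sim, duct_dir = duct_dir,
       first_year = sim$truths[[1]]$first_year,
       last_year = sim$truths[[1]]$first_year + n_years - 1L)
}

test_that("build_master compiles per-core metrics and honors the ID contract", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 3, n_cores = 2L, n_years = 30L)
  chron <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                        st$first_year, st$last_year)
  expect_s3_class(chron, "master_chronology")
  expect_identical(nrow(chron$rows), 2L * 30L)
  expect_identical(sort(unique(chron$rows$sample_id)),
                   c("SYN001a", "SYN001b"))

  # end-to-end conservation: ducts in = ducts out
  n_in <- sum(vapply(st$sim$files, function(f) {
    e <- read_measurements(f$txt)$entries
    sum(!e$is_sentinel)
  }, numeric(1)))
  expect_equal(sum(chron$rows$duct_production), n_in)

  # combining merges the a/b cores into one tree series
  tree <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                       st$first_year, st$last_year, combine = TRUE)
  expect_identical(nrow(tree$rows), 30L)
  expect_identical(unique(tree$rows$sample_id), "SYN001")
  expect_identical(sum(tree$rows$duct_production),
                   sum(chron$rows$duct_production))

  # unmatched stem fails before computing, naming the stem
  orphan <- file.path(st$duct_dir, "XX.csv")
  writeLines(c("sample_id,year,duct_area_mm2",
               sprintf("XX,%d,0.1", st$first_year)), orphan)
  expect_error(build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                            st$first_year, st$last_year),
               "XX")
  file.remove(orphan)

  # out-of-range years are an error, not a silent trim
  expect_error(build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                            st$first_year, st$last_year - 1L),
               "outside")
})

test_that("master CSV writing is deterministic and rebuild is idempotent", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 9)
  chron <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                        st$first_year, st$last_year,
                        log_path = file.path(dir, "run.log"))
  p1 <- file.path(dir, "master1.csv"); p2 <- file.path(dir, "master2.csv")
  write_master(chron, p1)
  chron2 <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                         st$first_year, st$last_year)
  write_master(chron2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(file.path(dir, "run.log")))
  expect_match(readLines(file.path(dir, "run.log")),
               "core_width_mm: 5.15", all = FALSE)

  back <- read_master(p1)
  expect_identical(nrow(back$rows), nrow(chron$rows))
  expect_equal(back$rows$duct_production, chron$rows$duct_production)
})

test_that("qc_checks flags implausible values and lists missing rings", {
  rows <- data.frame(
    sample_id = "QC01a", year = 2000:2003,
    duct_size_mm2 = c(0.05, 0.9, NA, 0.04),
    duct_production = c(2L, 3L, 0L, 1L),
    total_duct_area_mm2 = c(0.1, 2.7, 0, 0.04),
    duct_density_per_mm2 = c(0.2, 0.3, NA, -0.1),
    relative_duct_area_pct = c(5, 120, NA, 4),
    ring_width_mm = c(1, 2, 0, 1),
    ring_area_mm2 = c(5.15, 10.3, 0, 5.15))
  chron <- structure(list(rows = rows, metadata = list()),
                     class = "master_chronology")
  report <- qc_checks(chron)
  expect_match(report$flags$rule, "outside plausible band", all = FALSE)
  expect_match(report$flags$rule, "exceeds 100%", all = FALSE)
  expect_match(report$flags$rule, "negative value", all = FALSE)
  expect_identical(report$missing_rings$year, 2002L)
  expect_named(report$summary, "QC01a")

  # clean synthetic chronology is a negative control
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 5)
  clean <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                        st$first_year, st$last_year)
  expect_identical(nrow(qc_checks(clean)$flags), 0L)
})

test_that("plot_chronology writes a PNG and validates its inputs", {
  dir <- withr::local_tempdir()
  st <- make_study(dir, seed = 13)
  chron <- build_master(st$duct_dir, st$sim$site_rwl, core_geometry(5.15),
                        st$first_year, st$last_year)
  out <- file.path(dir, "density.png")
  plot_chronology(chron, "duct_density_per_mm2", out)
  expect_true(file.exists(out) && file.size(out) > 0)

  expect_error(plot_chronology(chron, "colour", out), "valid fields")
  empty <- structure(list(rows = chron$rows[0, ], metadata = list()),
                     class = "master_chronology")
  expect_error(plot_chronology(empty, "duct_density_per_mm2", out),
               "nothing to plot")
})
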