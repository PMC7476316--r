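test_that("unstandardized metrics follow the per-ring definitions", {
  tab <- dated_duct_table("MET01a", 2000,
                          list(c(0.5, 0.3), numeric(0), 0.25))
  rows <- unstandardized_metrics(tab)
  expect_equal(rows$duct_size_mm2, c(0.4, NA, 0.25))
  expect_identical(rows$duct_production, c(2L, 0L, 1L))
  expect_equal(rows$total_duct_area_mm2, c(0.8, 0, 0.25))
})

test_that("standardization divides by ring area (width x core width)", {
  tab <- dated_duct_table("MET01a", 2000, list(c(0.5, 0.3)))
  series <- ring_width_series("MET01a", 2000, 2.0)
  rows <- standardized_metrics(unstandardized_metrics(tab), series,
                               core_geometry(5.15))
  expect_equal(rows$ring_area_mm2, 10.3)
  expect_equal(rows$duct_density_per_mm2, 2 / 10.3)       # 0.194175...
  expect_equal(rows$relative_duct_area_pct, 100 * 0.8 / 10.3)  # 7.76699...%

  # missing ring: production kept, standardized metrics NA
  tab2 <- dated_duct_table("MET01a", 2000, list(0.5, numeric(0)))
  series2 <- ring_width_series("MET01a", 2000, c(1.0, 0))
  rows2 <- standardized_metrics(unstandardized_metrics(tab2), series2,
                                core_geometry(5.15))
  expect_equal(rows2$ring_area_mm2[2], 0)
  expect_true(is.na(rows2$duct_density_per_mm2[2]))
  expect_true(is.na(rows2$relative_duct_area_pct[2]))
  expect_identical(rows2$duct_production[2], 0L)

  # ductless normal ring: zero density and relative area
  tab3 <- dated_duct_table("MET01a", 2000, list(numeric(0)))
  rows3 <- standardized_metrics(unstandardized_metrics(tab3), series,
                                core_geometry(5.15))
  expect_equal(rows3$duct_density_per_mm2, 0)
  expect_equal(rows3$relative_duct_area_pct, 0)

  # coverage failure propagates from the slice
  tab4 <- dated_duct_table("MET01a", 1999, list(0.5, 0.5))
  expect_error(standardized_metrics(unstandardized_metrics(tab4), series,
                                    core_geometry(5.15)), "1999")
})

test_that("metric identities and scaling hold on random chronologies", {
  set.seed(11)
  for (rep in 1:20) {
    truth <- simulate_core(core_sim_params(n_years = 60L), seed = rep)
    tab <- truth_duct_table(truth)
    series <- truth_ring_series(truth)
    rows <- standardized_metrics(unstandardized_metrics(tab), series,
                                 core_geometry(5.15))
    pos <- rows$duct_production > 0
    expect_equal(rows$duct_size_mm2[pos] * rows$duct_production[pos],
                 rows$total_duct_area_mm2[pos], tolerance = 1e-9)
    expect_equal(rows$ring_area_mm2, rows$ring_width_mm * 5.15)
    ok <- rows$ring_area_mm2 > 0
    expect_equal(rows$duct_density_per_mm2[ok],
                 rows$duct_production[ok] / rows$ring_area_mm2[ok],
                 tolerance = 1e-12)
    expect_equal(rows$relative_duct_area_pct[ok],
                 100 * rows$total_duct_area_mm2[ok] / rows$ring_area_mm2[ok],
                 tolerance = 1e-12)

    # scaling all duct areas by c scales totals, sizes and relative area
    c_scale <- 2.5
    tab_s <- dated_duct_table(tab$sample_id, tab$first_year,
                              lapply(tab$ducts, function(a) a * c_scale))
    rows_s <- standardized_metrics(unstandardized_metrics(tab_s), series,
                                   core_geometry(5.15))
    expect_equal(rows_s$total_duct_area_mm2,
                 rows$total_duct_area_mm2 * c_scale)
    expect_equal(rows_s$duct_size_mm2[pos],
                 rows$duct_size_mm2[pos] * c_scale)
    expect_identical(rows_s$duct_production, rows$duct_production)
    expect_equal(rows_s$duct_density_per_mm2, rows$duct_density_per_mm2)
    expect_equal(rows_s$relative_duct_area_pct[ok],
                 rows$relative_duct_area_pct[ok] * c_scale)
  }
})

test_that("unit geometry reduces standardized metrics to counts and totals", {
  tab <- dated_duct_table("UNI01a", 2000, list(c(0.2, 0.3), 0.1))
  series <- ring_width_series("UNI01a", 2000, c(1, 1))
  rows <- standardized_metrics(unstandardized_metrics(tab), series,
                               core_geometry(1))
  expect_equal(rows$duct_density_per_mm2, rows$duct_production)
  expect_equal(rows$relative_duct_area_pct,
               100 * rows$total_duct_area_mm2)
})

make_core_rows <- function(id, ducts, widths, first_year = 2000,
                           core_width = 5.15) {
  tab <- dated_duct_table(id, first_year, ducts)
  series <- ring_width_series(id, first_year, widths)
  standardized_metrics(unstandardized_metrics(tab), series,
                       core_geometry(core_width))
}

test_that("combine_cores sums counts, areas and ring areas then recomputes ratios", {
  a <- make_core_rows("TREE01Aa", list(c(0.5, 0.3)), 2.0)
  b <- make_core_rows("TREE01Ab", list(0.5), 1.5)
  comb <- combine_cores(list(a, b), core_geometry(5.15))
  expect_identical(comb$sample_id, "TREE01A")
  expect_identical(comb$duct_production, 3L)
  expect_equal(comb$total_duct_area_mm2, 1.3)
  expect_equal(comb$ring_area_mm2, 18.025)
  expect_equal(comb$duct_density_per_mm2, 3 / 18.025)      # 0.166435...
  expect_equal(comb$relative_duct_area_pct, 130 / 18.025)  # 7.21220...%
  expect_equal(comb$duct_size_mm2, 1.3 / 3)

  # a year present in only one core passes through unchanged
  a2 <- make_core_rows("TREE01Aa", list(0.4, 0.2), c(1.0, 1.2),
                       first_year = 2000)
  b2 <- make_core_rows("TREE01Ab", list(0.1), 1.0, first_year = 2000)
  comb2 <- combine_cores(list(a2, b2), core_geometry(5.15))
  only_a <- comb2[comb2$year == 2001, ]
  expect_equal(only_a$total_duct_area_mm2, 0.2)
  expect_equal(only_a$ring_area_mm2, 1.2 * 5.15)

  # both cores ductless: zero production and zero density
  a3 <- make_core_rows("TREE01Aa", list(numeric(0)), 1.0)
  b3 <- make_core_rows("TREE01Ab", list(numeric(0)), 1.0)
  comb3 <- combine_cores(list(a3, b3), core_geometry(5.15))
  expect_identical(comb3$duct_production, 0L)
  expect_equal(comb3$duct_density_per_mm2, 0)
  expect_true(is.na(comb3$duct_size_mm2))

  # prefix mismatch rejected
  expect_error(combine_cores(list(a, make_core_rows("OTHERb", list(0.1), 1)),
                             core_geometry(5.15)),
               "prefix")
})

test_that("combination conserves total duct production", {
  set.seed(23)
  for (rep in 1:10) {
    t1 <- simulate_core(core_sim_params(sample_id = "CONS01a",
                                        n_years = 40L), seed = rep)
    t2 <- simulate_core(core_sim_params(sample_id = "CONS01b",
                                        n_years = 40L), seed = rep + 100)
    r1 <- standardized_metrics(unstandardized_metrics(truth_duct_table(t1)),
                               truth_ring_series(t1), core_geometry(5.15))
    r2 <- standardized_metrics(unstandardized_metrics(truth_duct_table(t2)),
                               truth_ring_series(t2), core_geometry(5.15))
    comb <- combine_cores(list(r1, r2), core_geometry(5.15))
    expect_identical(sum(comb$duct_production),
                     sum(r1$duct_production) + sum(r2$duct_production))
    expect_equal(sum(comb$total_duct_area_mm2),
                 sum(r1$total_duct_area_mm2) + sum(r2$total_duct_area_mm2))
  }
})
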