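# ductchron

Axial resin ducts in conifer secondary xylem store and deliver oleoresin,
the tree's principal defense against bark beetles and pathogens. Because
ducts are permanently embedded in dated annual rings, a sanded increment
core yields a retrospective, year-by-year record of defense investment.
`ductchron` turns the raw measurement files such a study produces — ImageJ
"Results" tables of per-duct ellipse areas and Tucson-format (RWL)
ring-width files — into a dated master chronology of five defense metrics,
for dendroecologists quantifying duct chronologies across many cores.

## The metrics

For each core and calendar year *t*, with duct areas
*a₁ … a_k* (mm²) measured in that ring, ring width *w_t* (mm) and average
core width *c* (mm):

| metric | definition | type |
|---|---|---|
| duct size (mm²) | mean(*aᵢ*) — NA when *k* = 0 | unstandardized |
| duct production (no. yr⁻¹) | *k* | unstandardized |
| total duct area (mm² yr⁻¹) | Σ *aᵢ* | unstandardized |
| duct density (no. mm⁻² yr⁻¹) | *k* / *A_t* | standardized |
| relative duct area (% ring) | 100 · Σ *aᵢ* / *A_t* | standardized |

where ring area *A_t* = *w_t* · *c* approximates the sampled ring surface.
The standardized metrics adjust for growth rate; a missing (locally
absent) ring has *w_t* = 0 and its standardized metrics are NA. ImageJ
records areas in square inches; they are converted once, exactly, by
645.16 mm² in⁻².

Calendar years are attached by the sentinel convention: ducts are measured
oldest ring first, and a zero-area "fake" measurement marks each ring
boundary, so the stream splits into one group per sentinel; an empty group
is a ductless or missing ring. `verify_alignment()` cross-checks the
result against the RWL record (ring count, span, no ducts in zero-width
rings) and reports rather than errors, so the source TXT can be fixed.

Replicate cores of a tree (IDs differing in the final letter, e.g.
`SNF383La`/`SNF383Lb`) can be summed: counts, duct areas and ring areas
are added per year and the ratios recomputed from the sums, which keeps
size × production = total exact at tree level.

## Worked example

Simulated fixtures stand in for scanned cores (the generator writes
ImageJ-style TXT and Tucson RWL files with known ground truth):

```r
library(ductchron)

sim <- simulate_cores(n_cores = 2, n_years = 30, seed = 42, out_dir = "demo/fx")
for (f in sim$files) {
  tab <- assign_years(read_measurements(f$txt), first_year = 1900)
  write_dated_ducts(tab, file.path("demo/ducts", paste0(tab$sample_id, ".csv")))
}
chron <- build_master("demo/ducts", sim$site_rwl, core_geometry(5.15),
                      first_year = 1900, last_year = 1929)
chron
#> <master_chronology> 60 rows, 2 series, years 1900-1929, core width 5.15 mm
head(chron$rows, 4)
#>   sample_id year duct_size_mm2 duct_production total_duct_area_mm2
#> 1   SYN001a 1900    0.05096764               3          0.15290292
#> 2   SYN001a 1901            NA               0          0.00000000
#> 3   SYN001a 1902    0.06322568               1          0.06322568
#> 4   SYN001a 1903    0.06838696               5          0.34193480
#>   duct_density_per_mm2 relative_duct_area_pct ring_width_mm ring_area_mm2
#> 1           0.25661862              1.3079246          2.27       11.6905
#> 2           0.00000000              0.0000000          2.00       10.3000
#> 3           0.09471939              0.5988698          2.05       10.5575
#> 4           0.46012976              3.1466875          2.11       10.8665
```

Row 2 is a ring with no ducts: production 0, size NA, density 0. The
per-area duct initiation rate pools all rings (here the generator's true
rate was 0.2 ducts mm⁻²):

```r
est <- estimate_duct_rate(chron$rows)
#> duct rate: 0.1989 +/- 0.0191 ducts/mm^2 over 58 rings

qc_checks(chron)
#> <qc_report> 0 flag(s), 2 missing ring(s), 2 core(s)
```

`write_master()` emits the chronology CSV; `plot_chronology()` draws one
metric per core over years with missing rings as gaps.

The same workflow runs from a shell via the `exec/ductchron` script
(`simulate`, `add-years`, `compile`, `metrics`, `combine`, `qc`, `plot`),
with a YAML `--config` file supplying defaults that flags override.

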