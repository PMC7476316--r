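---
title: "Building resin duct chronologies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building resin duct chronologies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductchron)
```

## The measurement model

A conifer increment core is sanded, crossdated and scanned; every axial
resin duct in every ring is outlined as an ellipse in ImageJ, which
records its area in square inches. Measurement proceeds from the oldest
ring (toward the pith) to the newest (toward the bark), and a zero-area
"fake" measurement — a *sentinel* — is inserted at every ring boundary.
The exported Results table is therefore a flat, ordered stream in which
ring structure is encoded purely by the sentinels:

* a ring with ducts contributes its duct areas followed by one sentinel;
* a ring with no ducts contributes a lone sentinel;
* a missing (locally absent) ring contributes a second consecutive
  sentinel at the same boundary.

`assign_years()` inverts this encoding: it splits the stream into one
group per sentinel and dates group *k* (zero-based) to
`first_year + k`, where `first_year` — the year of the innermost measured
ring — is the one piece of dating information the user must supply. The
algorithm cannot distinguish "ring present, no ducts" from "ring absent";
both are empty groups. That ambiguity is resolved downstream by
`verify_alignment()`, which checks the dated table against the ring-width
record: the final year must match the declared last measured year, every
dated year must fall inside the series span, and a zero-width (missing)
ring must carry zero ducts. The check returns a report instead of
erroring because the recommended fix is editing the source TXT, not
aborting a batch.

Parsing enforces one structural invariant early: the final entry of a
measurement file must be a sentinel. Without it the newest ring would be
silently dropped by the splitter, which is exactly the kind of off-by-one
that is cheap to detect at ingest and expensive to find later.

## Metrics and their degenerate cases

Five per-ring metrics are computed. Unstandardized: duct size (mean area,
mm²), duct production (count), total duct area (mm²). Standardized, i.e.
adjusted for growth rate: duct density = production / ring area and
relative duct area = 100 × total / ring area, with ring area = ring width
× core width. Core width is a single average per core (e.g. 5.15 mm, the
inside diameter of a standard borer); per-ring core widths are out of
scope.

Degenerate cases are fixed as follows and tested:

* no ducts in a normal ring: size NA, production 0, total 0, density 0,
  relative area 0;
* missing ring (width 0): ring area 0, density and relative area NA —
  NA rather than 0 or infinity, so the undefined ratio propagates
  honestly into downstream statistics; production and total are kept;
* relative area above 100% is flagged by QC, never clamped.

Values are kept at full double precision throughout; rounding to 6
significant digits happens only when `write_master()` serializes the CSV,
which also makes rebuilds byte-identical.

Replicate cores of one tree (core letter last in the sample ID) are
combined by summing production, total duct area and ring area per year
over the cores with data in that year, then recomputing size, density and
relative area from the sums. Summing, rather than averaging per-core
ratios, reduces the zero-count problem that motivates taking two 5.15 mm
cores in the first place, and it preserves the identity
size × production = total exactly at tree level — averaging ratios breaks
it. Where only one core covers a year, the combined row equals that
core's row.

## File formats

**Tucson RWL.** Series ID in columns 1–8, then a decade year, then up to
ten integer widths per line. The terminal stop marker doubles as the
precision flag: `999` means hundredths of a millimetre, `-9999`
thousandths — the two precisions ring-width software offers when saving
RWL. Detection is per series and never mixes dialects within one. Widths
are concatenated in file order, treating the per-line decade field as a
label; duplicate or out-of-order decade lines are errors. Up to three
leading lines that do not look like data (no parseable year token) are
skipped as optional headers; a data-like line with a corrupt value field
is a parse error naming the line. A series without a stop marker draws a
warning and is assumed to be in the 0.01 mm dialect. On write, widths not
representable at the requested precision are rounded half-up with a
warning, so information loss is never silent.

**ImageJ Results.** Tab- or comma-delimited with a header containing an
`Area` column (case-insensitive; tab preferred when both split). Areas
are always interpreted as square inches and converted by the exact factor
645.16; there is no per-file unit autodetection, because the scale is set
once from the scan DPI. The `Label` column is ignored for identity — the
filename stem is the sample ID, and it must match the RWL series ID
exactly and case-sensitively (the trailing lowercase core letter is
significant). Sentinels are entries with area ≤ 0 by default; the
threshold is configurable because a stray one-pixel click can record a
tiny nonzero area. A non-sentinel area below 10⁻⁵ in² (≈ 0.0065 mm²,
smaller than any plausible duct) draws a warning prompting the user to
verify their fakes were recorded as zeros.

## The synthetic-core generator

`simulate_core()` emulates the statistical shape of real core data so the
whole pipeline is testable with known ground truth:

* ring widths: `max(0, width_init · exp(-decay · t) + AR(1) noise)` — a
  negative-exponential age trend with autocorrelated year-to-year
  variation, the standard caricature of a raw ring-width series;
* missing rings injected with a fixed probability, forcing width and duct
  count to zero together;
* duct counts Poisson with mean `duct_rate × ring area`, consistent with
  density being the rate per mm² of ring;
* duct areas lognormal, truncated below at 0.005 mm² so no synthetic duct
  can be confused with a sentinel after export rounding.

Defaults (2.0 mm initial width, decay 0.01 yr⁻¹, AR coefficient 0.5,
innovation sd 0.2 mm, rate 0.2 ducts mm⁻², lognormal meanlog log(0.05)
and sdlog 0.4, missing probability 0.02, core width 5.15 mm) describe a
moderately fast-growing pine on a 5.15 mm core: mean duct size around
0.05 mm², about two ducts per ring, and roughly 13% ductless years — the
zero-inflation regime that motivates the two-cores-per-tree
recommendation. `emit_fixture_files()` writes the matching ImageJ-style
TXT (areas converted to in² and written with 6 decimal places) and RWL
files. Six decimals, not fewer: at 3 decimals a typical duct
(≈ 8 × 10⁻⁵ in²) would round to 0.000 and become indistinguishable from a
sentinel, corrupting the ring structure the file exists to encode; 6
decimals keeps every duct above the floor representable while still
exercising realistic precision loss (up to ±0.5 × 10⁻⁶ in² ≈
3.2 × 10⁻⁴ mm² per area, which round-trip tests must and do tolerate).

What the generator does *not* emulate: climate signals in widths or duct
rates, within-ring duct positioning, measurement error in ellipse
fitting, observer misses, or cracked/damaged cores. Passing tests
demonstrate that the bookkeeping — grouping, dating, unit conversion,
metric arithmetic, aggregation — is exact, not that the biology is
realistic.

## Estimating the duct initiation rate

`estimate_duct_rate()` regresses duct production on ring area through the
origin with inverse-ring-area weights. Under the Poisson picture the
count variance grows with ring area, so inverse-area weights are the
inverse-variance choice; the estimator collapses to total ducts / total
ring area, and its standard error then has the correct sampling scale
(an unweighted fit through the origin gives the same order of estimate
but an SE that is too small when large rings dominate). Missing rings
carry no exposure and are excluded. On simulated cores of 500 rings the
±3 SE interval covers the true rate in ≈98% of seeds, consistent with the
nominal three-sigma level.

## Numerical and design choices

* Unit conversion uses the literal constant 645.16 mm² in⁻² so the
  conversion is exact in decimal, not 25.4² re-derived in binary.
* Half-up rounding (RWL write, fixture export) adds a tolerance of 10⁻⁹
  relative before flooring, so decimal inputs stored fractionally below
  the half-way point in binary still round up as a human would expect.
* Identity checks (size × production = total) use 10⁻⁹ relative
  tolerance; observed errors are at the 10⁻¹⁶ level.
* `build_master()` treats years outside the declared
  `[first_year, last_year]` window as errors rather than trimming them:
  an out-of-window year means the dating is wrong at source, and
  silently dropping it would hide exactly the misalignment the QC
  workflow is built to surface. Likewise an unmatched sample ID fails the
  whole build before any computation, listing every unmatched stem
  against the available series.
* The master table is sorted by sample ID then year and rounded only at
  write time, so identical inputs produce a byte-identical CSV.
* QC rules are pure predicates with configurable thresholds (duct size
  plausibility band default 0.001–0.5 mm²; relative area > 100%; any
  negative value; missing rings listed for review). Test problem sizes —
  1,000 random streams for the splitter oracle, 100 collections for RWL
  round trips, 100 simulated cores end-to-end, 100 seeds × 500 rings for
  rate recovery — were chosen to exercise each property across its input
  space while keeping the suite fast to run routinely.

## Limitations

Crossdating, detrending and chronology statistics belong to upstream
dendro tools and are out of scope, as is any automated duct detection
from images: duct identification remains a human task at a dissecting
scope. The pipeline assumes one constant core width per core, exact
ID matching between TXT stems and RWL series, and the sentinel discipline
described above; a measurement file that violates the discipline in ways
that keep the sentinel count correct (e.g. a duct recorded in the wrong
ring) is detectable only through the width cross-check or by eye.
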