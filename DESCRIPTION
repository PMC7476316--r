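Package: ductchron
Title: Resin Duct Chronologies from Tree-Ring Measurements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dated master chronologies of axial resin duct defense
    metrics for conifer tree cores. Reads ImageJ Results tables of per-duct
    ellipse areas (square inches, sentinel-delimited by ring), assigns
    calendar years to each duct honoring ductless and locally absent
    (missing) rings, reads and writes Tucson-format (RWL) ring-width files
    in both 0.01 mm and 0.001 mm precision dialects, and computes five
    per-ring duct metrics: duct size, duct production, total duct area,
    duct density, and relative duct area, the latter two standardized by
    ring area (ring width times core diameter). Supports combining
    replicate cores per tree, quality-control screening, plotting, a
    synthetic-core simulator with known ground truth, and a command-line
    interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
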