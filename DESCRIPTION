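Package: amazonfire
Title: Fire-Deforestation Decoupling Diagnostics for the Brazilian Amazon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to re-examine the coupling between active-fire activity
    and deforestation in the Brazilian Amazon biome. Classifies satellite
    active-fire detections into deforestation, maintenance, and forest
    (understory) fires from fire persistence and landscape thresholds;
    computes Mann-Kendall/Theil-Sen trends, fires-per-area-deforested
    ratio series and policy-phase regressions; maps standardized
    fire-count anomalies and their areal extent; characterizes fire
    intensity through fire radiative power percentiles and a segmented
    (breakpoint) trend fit; decomposes gridded fire variability into
    EOF/principal-component modes; and runs carbon-monoxide trend and
    sensitivity analyses. A seeded synthetic-data generator emulates the
    study inputs with known ground truth so the whole pipeline is
    testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
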