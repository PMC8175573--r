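Package: enucleoscreen
Title: Simulation and Analysis of Imaging-Based Erythroid Enucleation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, tested pipeline for high-content imaging screens
    of erythroid enucleation. Simulates multi-channel fluorescence plates of
    immortalized erythroid progenitor cells with known state composition and
    compound effects; detects and measures cells in field images; classifies
    each object by a three-signal truth table (lineage reporter, cell-permeant
    and cell-impermeant DNA dyes); computes enucleation frequency and
    plate-normalized fold changes against in-plate vehicle controls; calls hit
    compounds by a dual enucleation/viability criterion; and cross-checks the
    imaging estimates with a flow-cytometry-style gating stage and a gene-list
    overlap statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
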