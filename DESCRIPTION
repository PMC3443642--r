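Package: rhmapper
Title: Radiation Hybrid Map Construction and Deletion Analysis for Wheat
    Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds radiation hybrid (RH) maps from binary retention/deletion
    genotype matrices of aneuploid wheat panels: two-point breakage statistics
    and centiRay distances, iterative LOD-gated framework ordering with a
    ripple refinement, deletion-bin assignment from anchor markers, calling
    and sizing of radiation-induced deletions, per-bin resolution and
    breakage/repair (BR) and crossing-over (CO) frequency statistics, and a
    Pearson correlation suite for the BR-CO interaction.  Includes a
    chromatin-openness-driven simulator of RH panels for validation, and
    packaged per-bin and per-contig reference tables for wheat chromosome 3B.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
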