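Package: rgcscreen
Title: Relative Group Contribution Model for Ligand-Efficiency-Guided
    Fragment Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the relative group contribution (RGC) model for
    ligand-efficiency metrics in fragment-based drug design. Computes the
    apparent total ligand efficiency (LETapp) of multi-fragment compounds
    under arithmetic and weighted root-mean-square averaging, the dynamic
    subtractive-average requirement (LE-delta) for fragments whose
    efficiency is not yet known, and runs multi-pocket combinatorial
    fragment screens in which low-efficiency fragments can be rescued by
    high-efficiency partners. Includes readers and writers for fragment
    library tables and SDF records, screen reports as CSV and JSON, and a
    synthetic-data generator for linked drug-sized molecules with
    controllable additivity noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
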