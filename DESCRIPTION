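Package: squeezecyto
Title: Electromechanical Analysis of Single Cells in Microfluidic
    Constriction Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts raw constriction-channel measurements of single
    cells (two-frequency impedance traces and high-speed-camera
    aspiration-length trajectories) into three intrinsic biophysical
    markers: specific membrane capacitance, cytoplasm conductivity and
    instantaneous Young's modulus.  Provides the lumped equivalent-circuit
    impedance model and its inversion, the polynomial viscoelastic entry
    model relating normalized aspiration lengths to the pressure-to-modulus
    ratio and the cell-wall friction coefficient, marker extraction from
    raw streams, a seeded synthetic-cohort simulator for end-to-end
    parameter-recovery validation, and readers/writers for the deposited
    per-cell record layouts with cohort summary statistics.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
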