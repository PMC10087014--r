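Package: cloneviz
Title: Visualization and Estimation Toolkit for Tumor Clonal Evolution
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data model and algorithms for analysing and visualising tumor
    clonal evolution from cancer cell fraction (CCF) tables. Provides a
    validated clonal-evolution container with parental relations, a
    structured validity check, exhaustive enumeration of alternative
    phylogenies compatible with a CCF table, fully automatic time-point
    interpolation, therapy-effect estimation, phylogeny-aware color coding,
    and renderer-independent geometry plus SVG/PNG rendering for shark
    (graph), dolphin (fish-plot style) and plaice (allele-aware, mirrored)
    plots. Includes a seeded simulator of valid clonal evolutions and a
    file-based command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
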