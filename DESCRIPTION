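Package: neckROM
Title: Collision-Terminated Range-of-Motion Analysis for Digitized Vertebral Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual osteological range-of-motion (ROM) analysis for digitized
    vertebral columns. Reads per-vertebra triangle meshes (OBJ, PLY, STL) with
    labelled anatomical parts, poses them as an articulated rigid chain with
    pivots placed between the centra, and finds per-joint maximal lateral,
    dorsal and ventral rotations terminated by bone-on-bone contact under two
    intervertebral-spacing regimes: preserved spacing (PCVM, the osteological
    maximum) and minimum spacing with the centra in contact (MISM, the
    osteological minimum). Includes a deterministic parametric vertebra
    generator (amphicoelous centra, angled neural spines, paired zygapophyses,
    cervical ribs) so every stage is testable without scan data, a virtual
    line-fitting angle measurement with triplicate averaging, and circular
    statistics (descriptive summaries and Watson-Williams tests) for comparing
    mobility profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
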