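Package: vf2cortex
Title: Visual-Field ROIs from Microperimetry Projected onto Retinotopic V1,
    with Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Defines preferred retinal locus (PRL), unpreferred retinal locus
    (URL) and lesion projection zone (LPZ) regions from microperimetry
    fixation and sensitivity data (bivariate contour ellipse area fitting,
    binocular sensitivity fusion, scotoma trimming, URL placement), projects
    the visual-field regions onto retinotopically annotated V1 surface
    vertices (nearest-cell matching, one-ring mesh dilation to a minimum
    vertex count, non-V1 pruning, lowest-eccentricity LPZ, eccentricity
    bands), extracts hemisphere-normalized cortical thickness and NODDI
    metrics per region, and runs the group inference battery (Welch t,
    three-way mixed ANOVA/ANCOVA with Mauchly sphericity testing and
    Huynh-Feldt correction, Benjamini-Hochberg post-hocs). A synthetic-data
    generator emulates fixation clouds, sensitivity grids, cortical-
    magnification-weighted retinotopic meshes and per-vertex metric maps so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    igraph
Config/testthat/edition: 3
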