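Package: filatrack
Title: Tracking of Curvilinear Biopolymer Networks in Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Temporally consistent extraction and frame-to-frame tracking of
    curvilinear biopolymer networks (actin filaments, fibrin fibers,
    contractile rings) in 2D and 3D fluorescence time-lapse images. Per-frame
    centerline curves are dissected at network junctions, re-linked by a
    junction-local bipartite matching that combines tip orientation with
    temporal cues from the preceding frame, and associated across frames by
    a minimum path cover of a k-partite correspondence graph solved through
    bipartite reduction and the Hungarian algorithm. Includes synthetic-data
    generators for elongating semiflexible 2D filaments and affinely deformed
    3D fiber networks with ground truth, and analyses of elongation rate,
    ring constriction, nematic order, affine deformation recovery and
    tracking precision/recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
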