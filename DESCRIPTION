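Package: ctmap
Title: Computational Texture Mapping for Whole-Slide Tile Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational texture mapping (CTM) of whole-slide
    histology tile maps. Given per-tile tissue-texture labels and continuous
    lymphocyte scores from any upstream classifier, ctmap smooths tessellated
    texture maps by sliding-window majority vote, extracts tumour margins by
    morphological dilation, profiles per-sample texture composition, applies
    quantitative cohort quality control and N+/N- stratification, harmonises
    lymphocyte infiltration across clinical centres through texture-aware
    normalisation (relative lymphocyte proportions and the area-weighted
    infiltration index alpha), computes margin:non-margin enrichment scores,
    and exposes a thin association-statistics layer (Wilcoxon, Kruskal-Wallis,
    chi-square, Benjamini-Hochberg, 5-year Kaplan-Meier log-rank). A seeded
    synthetic-cohort generator emulates centre-specific sampling conventions
    so every stage is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
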