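Package: nephromorph
Title: Morphometry of Segmented Kidney Histology Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chronic kidney damage from multi-class segmentations of
    PAS-stained kidney tissue sections. Provides a 20-class renal taxonomy
    (cortex/medulla compartments, glomerular subclasses, proximal and distal
    tubules, tubular atrophy clusters, arteries with intimal thickening and
    lumen, arterioles with hyalinosis), readers and writers for label rasters
    and GeoJSON annotation sets, connected-component extraction with
    edge-bisection flagging, the full battery of nephron-size and
    nephrosclerosis measures (Weibel-Gomez glomerular volume, cortex per
    glomerulus, tubular areas, %GSG, %TA, %ITA, tubular-atrophy focus density,
    arteriolar-hyalinosis density and area with distance-based lesion merging,
    luminal stenosis of arteries), pixel-level inter-annotator agreement
    statistics, two 0-12 ordinal chronicity scores, and a seeded synthetic
    section generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
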