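Package: paddyphenom
Title: Leaf-Count-Aided Drought Phenotyping for Rice Genotype Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale image-phenotyping pipeline for discriminating
    drought-tolerant from drought-sensitive rice (Oryza sativa L.) genotypes
    from top-view RGB imagery. Counts leaves by detecting leaf tips as
    skeleton endpoints of an excess-green plant segmentation, derives
    tip-geometry traits (convex hull area, bounding box area, plant aspect
    ratio, leaves per convex hull area), computes a leaf-emergence-rate
    stress tolerance index with tolerance classification bands, accounts
    biomass composition from destructive records, and clusters genotypes on
    their trait vectors. Ships a procedural top-view rice plant generator
    with exact ground-truth tip annotations so the whole chain is testable
    without imagery downloads, plus YOLO-format label I/O so external
    detections can enter the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
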