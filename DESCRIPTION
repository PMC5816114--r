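Package: pelletmorph
Title: Morphometric Profiling of Mycelial Pellet Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the morphology of liquid-grown filamentous
    actinomycete cultures from whole-slide micrographs. Segments mycelial
    particles, measures twelve shape and texture features per particle
    (Feret diameters, circularity, roundness, box-counting fractal
    dimensions and others), describes each culture condition as a
    two-component bivariate Gaussian population of small and large pellets
    fitted by expectation-maximization, and scores cross-condition
    morphological similarity with per-feature Tukey HSD profiles and Tukey
    tests on principal-component scores projected into a reference
    condition's PCA space. Includes a synthetic-data generator that draws
    particle feature tables from a specified two-component population and
    renders artificial pellet micrographs with ground truth, plus
    spectrophotometric assay helpers for tyrosinase activity and
    actinorhodin concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
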