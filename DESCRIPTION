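Package: colonyGate
Title: Range-Gate Classification of Colonial Phytoplankton Morphospecies
    from Imaging Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automated classification of colonial Microcystis
    morphospecies and co-occurring phytoplankton genera from
    brightfield imaging-flow-cytometry particle images. Implements the
    ten standard particle properties (ABD diameter, Feret length,
    crack-boundary perimeter, roughness, Sobel edge gradient, grayscale
    and colour-channel statistics), per-class range-gate filter sets
    fitted from small training subsets with greedy feature reduction
    and an intersection narrowing step, and a validation suite
    (confusion matrices, balanced accuracy, Hellinger distance, SMAPE,
    Bray-Curtis dissimilarity, Kullback-Leibler divergence). A
    deterministic synthetic colony-image generator emulating seven
    morphological classes makes the whole pipeline testable end to end,
    including seasonal abundance time series across mesocosm tanks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
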