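Package: p16foci
Title: Quantification of p16-Positive Fibroblastic Foci with Survival and
    Spatial Transcriptomic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-pathology pipeline for scoring cellular senescence in
    fibrotic interstitial lung disease. Converts calibrated whole-slide
    annotations (tissue polygons plus p16-positive focus marks) into foci
    densities per 100 square millimetres of lung tissue and a p16-low/high
    dichotomy; evaluates diagnostic performance against multi-disciplinary
    diagnosis; estimates lung-transplant-free survival with Kaplan-Meier,
    log-rank and Cox proportional-hazards models; derives ROC-optimal
    density cutoffs; and analyses GeoMX-style digital spatial profiling
    counts (housekeeping and upper-quartile normalization, differential
    expression with false-discovery control, hierarchical clustering,
    principal components, gene-set enrichment). Seeded synthetic-data
    generators with serialized ground truth make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    fgsea,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
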