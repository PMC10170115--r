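Package: enteromap
Title: Spatial Organization and Motility Analysis for the Developing Enteric
    Nervous System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization of myenteric-plexus
    neurons in wholemount preparations and the motility of ex vivo intestinal
    segments. Implements conditional-intensity-function (CIF) maps of neighbor
    density around neurons, z-score-difference tests against hard-core
    complete-spatial-randomness nulls, stripe-periodicity estimation,
    area-based neuron and subtype counting, depth projection, cross-section
    muscle and nuclear-density measurements, spatiotemporal (kymograph) maps
    of tube diameter, and contraction detection and classification including
    baseline/tetrodotoxin comparisons. A seeded synthetic-data generator
    produces point patterns, wholemount image stacks, cross-section images,
    and motility videos with full ground truth, so every measurement stage can
    be validated end to end without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
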