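Package: lensoct
Title: Quantification of Crystalline Lens Opacities from Anterior Segment OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify crystalline lens opacities from anterior
    segment optical coherence tomography (AS-OCT) B-scans. Reads raw
    detector matrices, resizes them to display resolution by bicubic
    interpolation, composes whole-lens images from anterior and posterior
    halves, validates manual region segmentations, labels punctate (dot)
    opacities as connected components, and computes pixel intensity ratios
    (PIR) and pixel area ratios (PAR) for nuclear, cortical, posterior
    subcapsular and dot opacities, including central-versus-peripheral dot
    profiling. Also handles LOCS III photograding records with
    clinical-significance flagging and inter-grader bias, provides
    nonparametric cohort summaries and comparisons, and ships a seeded
    synthetic phantom generator with analytically known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
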