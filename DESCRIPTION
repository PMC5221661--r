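Package: neuromastsym
Title: Quantitative Bilateral Symmetry of Cranial Neuromast Patterns
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automated, reproducible pipeline for scoring left-right
    positional symmetry of cranial superficial neuromasts from fluorescence
    micrographs or digitized point tables. One side is mirrored, registered
    onto the other by a closed-form landmark (Procrustes) fit on canal
    neuromasts with score-maximizing refinement, rendered as dot masks, and
    scored with a pixel-wise Pearson colocalization coefficient; three
    seeded trials are averaged into a per-individual symmetry index.
    Includes region-of-interest morphometry (areas, counts, fragment
    tallies), cohort-level one-way ANOVA with post hoc Student's t-tests,
    a fully seeded synthetic-data generator with known ground truth
    (paired bilateral point patterns, rendered spot images, calibrated
    cohorts), Laplacian-of-Gaussian spot detection, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
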