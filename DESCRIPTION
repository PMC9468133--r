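Package: dentaxis
Title: Statistical Shape Modelling of Dental Root Axes from Crown Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based statistical shape models of human dentitions for
    predicting the three-dimensional axes of dental roots -- including roots
    of missing teeth -- from crown landmarks of an intraoral or plaster-cast
    surface scan. Implements a scale-preserving generalized Procrustes
    alignment, principal-component shape models, posterior reconstruction of
    unobserved landmarks from partial observations, total-least-squares tooth
    axis fitting, the three axis-accuracy metrics (angle alpha, cervical and
    apical axis distances), a leave-one-out cross-validation protocol with
    paired testing and Holm correction, and a synthetic dentition generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
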