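Package: survsurf
Title: Survival Surfaces and Contour Visualization for Time-to-Event Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits right-censored, interval-censored, and competing-risks
    survival models (Cox proportional hazards with Breslow baseline,
    parametric Weibull, Fine-Gray subdistribution hazard) and visualizes
    the predicted survival probability (or cumulative incidence) over
    time and a continuous covariate as a colored contour plot with a
    marginal covariate histogram, or as a 3D surface with confidence
    bands drawn as semitransparent layers. Includes a model-selection
    guide, concordance-index and integrated Brier score diagnostics, and
    a synthetic-data generator with known ground truth for testing and
    examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tibble,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    flexsurv,
    withr
Config/testthat/edition: 3
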