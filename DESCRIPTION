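Package: nutrigeom
Title: Nutritional Geometry Response Surfaces for Diet Experiments and
    Macronutrient-Supply Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nutritional geometry analyses of macronutrient
    composition and supply. Fits the Scheffe polynomial mixture-model
    family (Lawson-Willden linear, quadratic, special-cubic and
    full-cubic models plus a null model) to isocaloric diet-response
    experiments with AIC selection, and renders fitted response
    surfaces on right-angled mixture triangles with labelled isolines.
    Provides a penalized B-spline generalized additive mixed model
    engine for country-year macronutrient-supply panels: tensor-product
    smooths of nutrient supplies, GDP and time with country random
    intercepts, GCV smoothing selection, AIC candidate-model selection,
    and nutrient-space prediction surfaces with isocaloric lines and
    constant-ratio radials. Includes seeded synthetic-data generators
    with known ground truth for both input classes, CSV/JSON
    interchange, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    lhs,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
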