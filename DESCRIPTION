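Package: npheight
Title: Dietary Nitrogen and Phosphorus Intake and Adult Male Height Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking mean adult male height across countries and
    birth cohorts to per-capita dietary nitrogen (N) and phosphorus (P)
    intake. Builds annual N and P intake, the N:P mass ratio and
    animal/plant diet-group indicators from food-balance and
    food-composition tables over cohort growth windows; fits reduced major
    axis regressions, all-pairwise country-difference linear models with
    partial F statistics, and Bayesian model averaging under a Zellner
    g-prior (exact enumeration or MC3 sampling) for both height levels and
    cohort differences. Includes a synthetic country-by-cohort panel
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
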