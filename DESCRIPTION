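Package: dasypop
Title: Age-Stratified Dasymetric Population Downscaling on Covariate Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downscales census population counts from administrative units
    (townships nested in counties and cities) to 100-m grid cells by
    dasymetric mapping with a random-forest weighting layer, separately for
    total population and age groups (0-14, 15-59, 60-64, 65 and older).
    Implements the inhabited-zone mask, township density modelling with
    grid-search cross-validated random forests, mass-conserving allocation,
    per-cell age-structure proportions, and a validation battery: held-out
    model goodness-of-fit, total-versus-sum-of-ages consistency by city,
    coarse-source (county-level) validation, and spatial-variation-of-
    proportions comparisons against a county-share baseline. Includes a
    seeded synthetic landscape generator with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
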