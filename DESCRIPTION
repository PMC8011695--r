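Package: modelspace
Title: Model Projections in Kullback-Leibler Model Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the geometry of a set of fitted probability models and
    the location of the unknown data-generating process relative to that set.
    Count data recorded as replicate vectors of ordered category frequencies
    are fitted with nine classical count distributions through a
    reduced-parameter multinomial likelihood; all pairwise Kullback-Leibler
    divergences between fitted models are then computed exactly, symmetrized,
    and embedded in a low-dimensional plane with non-metric multidimensional
    scaling. A weighted nearest-neighbour estimator of the generating
    process' negative self-entropy, combined with AIC-based estimates of the
    negative cross-entropies, allows solving for the orthogonal projection of
    the generating process onto the model plane and its perpendicular
    distance from it, which can be contrasted with Akaike-weight model
    averaging. Includes synthetic-data generators with closed-form truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
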