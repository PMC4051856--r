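Package: neuritaxis
Title: Keller-Segel Modelling of Neurite Outgrowth Under Chemogradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling and quantification of growth-cone
    chemotaxis in microfluidic hydrogel chambers. Provides the exact
    eigenfunction-series solution of the diffusing guidance-cue field, a
    conservative finite-volume solver for the one-dimensional Keller-Segel
    growth-cone density equation with a receptor-saturating chemotaxis
    coefficient, staged estimation of the chemotaxis parameters (k, m) from
    displacement data, neurite morphometry (outgrowth histograms, wind-rose
    quadrant turning analysis, group comparisons), and a seeded synthetic
    experiment generator calibrated to published per-condition neurite
    length and turning distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
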