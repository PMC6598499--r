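Package: thermoniche
Title: Thermal Performance Curves and Phylogenetic Niche Structure for
    Microalgal Strain Panels
Version: 0.1.0
Authors@R:
    person("Willem", "Declerck", email = "wdeclerck@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating microalgal growth rates from chlorophyll
    fluorescence time series, fitting the Blanchard unimodal thermal
    performance curve by nonlinear least squares with parameter standard
    errors, deriving thermal optimum, maximum and performance-range metrics,
    and quantifying phylogenetic structure in the resulting thermal traits
    (Pagel's lambda, Blomberg's K, Mantel tests, penalized-likelihood rate
    smoothing). Includes a seeded synthetic-data generator that emulates a
    multi-strain temperature-gradient growth experiment with phylogenetically
    structured thermal optima, and a command-line pipeline that runs every
    stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
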