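Package: respirokin
Title: Growth Kinetics of Heterotrophic Bacteria from Batch Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive microbial growth kinetics from dissolved-oxygen
    respirograms recorded in aerated batch bioreactors with sequential
    substrate additions. The package segments respirograms into addition
    events, extracts dynamic oxygen uptake rates and oxygen consumption,
    converts them into yield coefficients and empirical specific growth
    rates via a COD mass balance, fits the unstructured growth models of
    Monod, Moser, Contois and Tessier by least-squared-error minimization,
    selects the best model per substrate, and reports substrate-degradation
    and cell-growth rate curves. A mechanistic reactor simulator with known
    ground truth (oxygen transfer, endogenous respiration, pulsed substrate
    additions, probe noise) supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
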