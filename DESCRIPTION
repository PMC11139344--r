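Package: ibdsel
Title: Selection on Environmentally Mediated Social Traits under Isolation by Distance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing selection on quantitative traits whose
    effects are mediated by lasting environmental state variables in
    patch-structured populations with isolation by distance. Provides exact
    Fourier analysis on the finite abelian group of patches, dispersal and
    commons-movement kernels, Wright-Fisher relatedness and scaled-relatedness
    coefficients, extended phenotypic effects, selection-gradient assembly,
    a lasting-commons model of inter-temporal helping and harming (altruism
    versus posthumous spite) with its convergence-stable singular strategy,
    and an individual-based Wright-Fisher lattice simulator that validates
    the analytic predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
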