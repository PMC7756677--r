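Package: mdtol
Title: Tolerance Intervals for Method Comparison Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the statistical intervals used to assess agreement
    between two clinical measurement methods on paired differences: the
    Bland-Altman agreement interval (with the confidence intervals around
    its bounds), the prediction / beta-expectation tolerance interval, and
    approximate and exact two-sided beta-gamma content tolerance intervals,
    the exact factor solved from its noncentral chi-square integral
    equation.  Provides the full mean-difference analysis pipeline
    (replicated designs, log/ratio scale with back-transformation,
    constant, two-threshold and percentage acceptance intervals, Sidak
    multiplicity adjustment, equivalence decision), mean-difference and
    ratio plots, and a Monte-Carlo engine that measures the effective
    predictive and confidence levels of every interval.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
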