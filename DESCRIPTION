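Package: mbdepth
Title: Modified Band Depth Statistics for Gene Expression Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Robust, nonparametric analysis of high-dimensional expression
    matrices based on the Modified Band Depth (MBD). Provides the efficient
    multiplicity-based MBD computation (with the naive pairwise definition
    retained as an oracle), depth of new observations with respect to a
    reference sample, center-outward orderings, depth-trimmed means, central
    band envelopes and scale curves, a depth-based two-sample rank test, and
    the DS and TAD depth-based classifiers, together with microarray-style
    preprocessing, between/within-groups gene ranking, synthetic two-class
    data generation and parallel-coordinate plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
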