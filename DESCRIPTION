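Package: rough3wd
Title: Sequential Three-Way Decision Classification with
    Decision-Theoretic Rough Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-way (accept/defer/reject) classification of tabular
    clinical data with decision-theoretic rough sets.  Implements the
    classical loss-matrix machinery that induces the (alpha, beta)
    probability thresholds from a 3x2 cost matrix, sequential
    decision-theoretic rough sets over multilevel equivalence
    granulations, and a generalized sequential engine that granulates
    the universe with Bray-Curtis-style similarity classes thresholded
    at xi, scores objects with covering-based rough membership
    functions (minimum, maximum, average), and iteratively exhausts the
    boundary region under a schedule of relaxing thresholds.  Includes
    worked clinical fixtures, a synthetic clinical-table generator,
    accuracy reporting and threshold-sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
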