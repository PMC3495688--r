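Package: shadowreg
Title: Reference-Free Estimation of Sequencing Error Rates by Shadow Regression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Estimates per-read and per-position sequencing error rates from
    short-read data without a reference genome. The method exploits the linear
    relationship between the copy number of a read and the total count of its
    "shadows" (reads differing from it by one or two substitutions, insertions
    or deletions): the slope of a robust regression of shadow count on read
    count transforms directly into an error rate. Includes a mismatch-counting
    comparator against a reference sequence, a repetitive-genome diagnostic,
    a coverage-adequacy check, and a short-read simulator with independent and
    dependent (error-burst) position-specific error models for validating the
    estimator against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
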