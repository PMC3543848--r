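Package: hedgedev
Title: Development and Validation of Boolean Search Strategies for
    Bibliographic Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating highly sensitive boolean
    search strategies ("hedges" or "search filters") for bibliographic
    databases such as OvidSP EMBASE and MEDLINE.  Provides an Ovid-dialect
    query engine (boolean operators, ADJn proximity, truncation and
    wildcards, field codes) that runs against local labelled corpora,
    retrieval diagnostics (sensitivity against dual gold standards,
    precision, number needed to read), combinatorial construction of
    sensitivity-maximizing and sensitivity/precision-balanced strategies
    with NOT-exclusion refinement, exact paired and unpaired tests for
    comparing strategies, and a synthetic corpus generator so that every
    stage is testable without access to the live databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
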