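Package: explantr
Title: Retrieval Analysis of Explanted UHMWPE Joint-Replacement Liners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized retrieval-analysis stack for explanted ultrahigh
    molecular weight polyethylene (UHMWPE) liners from total joint
    replacements. Converts infrared line scans into depth profiles of the
    oxidation, trans-vinylene and crystallinity indexes and extracts the 15
    standardized per-liner indexes; evaluates Vickers and instrumented
    (Oliver-Pharr) microindentation properties; validates and merges
    multi-center per-liner records into a single database; and computes the
    associated correlation, power-law, boxplot and two-group statistics.
    Includes a synthetic-data generator that emulates camel-shaped oxidation
    depth profiles, indentation load-depth-time curves and whole retrieval
    cohorts so that every stage is testable without physical specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    readxl,
    pracma,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
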