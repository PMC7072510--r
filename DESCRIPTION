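Package: mnquant
Title: Quantitative Micronucleus Scoring from Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, scriptable implementation of single-cell quantitative
    imaging microscopy for micronucleus enumeration. Segments Hoechst-stained
    nuclei with a fixed-threshold primary mask, approximates cell bodies with
    ring-shaped secondary masks, detects micronucleus spots with size and
    intensity filters, and aggregates per-well micronucleus frequencies into
    dose-response summaries, gene-silencing fold changes, and rank-based
    two-sample statistics. Ships a synthetic fluorescence-field generator with
    planted ground truth plus independent rule checkers, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
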