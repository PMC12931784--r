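Package: zefmea
Title: Consensus-Aware Fuzzy FMEA Risk Prioritization with BWM and MABAC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Failure Mode and Effects Analysis (FMEA) under uncertainty:
    triangular fuzzy arithmetic, Z-number and ZE-number reliability
    modelling in which expert confidence is moderated by group consensus
    votes, fuzzy Best-Worst Method criteria weighting, and ranking of
    failure modes by the Multi-Attributive Border Approximation area
    Comparison (MABAC) method.  Includes a packaged medicinal plant
    extraction case study, a synthetic expert-panel generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
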