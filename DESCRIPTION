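Package: meltprint
Title: Melting-Fingerprint Analysis for ISSR-HRM Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species identification from high-resolution melting
    (HRM) profiles of inter-simple sequence repeat (ISSR) amplicons.
    Simulates multi-peak melt curves with replicate jitter and population
    offsets, extracts melting fingerprints (pre/post-melt normalization,
    smoothed negative-derivative curves, prominence-based peak calling with
    sub-grid Tm refinement), matches fingerprints against a reference
    library by tolerance-based dynamic-programming peak alignment, classifies
    queries with single primers or primer combinations, computes
    primer-set discrimination matrices, and evaluates performance with
    one-vs-rest confusion matrices (accuracy, precision, sensitivity,
    specificity) aggregated per primer and per species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
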