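Package: pergdwt
Title: Discrete Wavelet Analysis of Pattern Electroretinogram Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies macular cone function from pattern
    electroretinogram (PERG) recordings using the periodized discrete
    wavelet transform. Screens candidate mother wavelets by their
    energy-to-entropy ratio, extracts participant-averaged time-frequency
    energy indices, compares normal and macular-predominant inherited
    retinal disease groups with nonparametric statistics under false
    discovery rate control, selects a minimal coefficient set whose
    inverse transform preserves the canonical N35/P50/N95 peaks, and
    benchmarks wavelet indices against the conventional |P50-N35| and
    |N95-P50| amplitude markers. Includes a synthetic cohort generator so
    the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
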