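Package: hetloop
Title: Mitotic Chromatin Loop Organisation over Heterochromatin Inserts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analyses of how large heterochromatin domains alter
    mitotic chromosome organisation. Provides binned metaphase-chromosome
    intensity profiling with rule-based signal/control region selection and
    Kolmogorov-Smirnov comparison, ChIP-qPCR percent-input enrichment
    statistics, an event-driven condensin loop-extrusion simulator with
    region-dependent loading, layer-model contact sampling with contact
    probability P(s) estimation, N50-based curve truncation and drop-off
    detection, plus seeded synthetic-data generators for every input so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
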