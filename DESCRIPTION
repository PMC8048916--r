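Package: clamap
Title: Quantitative Analysis of Multicolor Retrograde Tracing Data from the Claustrum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the quantitative analysis of multicolor retrograde
    tracing experiments mapping claustrocortical projections. Registers
    per-slice neuron coordinate tables to a reference (retrosplenial-
    projecting) population, classifies neurons into claustrum core and
    dorsal/ventral shell using a closest-90-percent convex polygon, builds
    binned spatial density maps with Otsu module boundaries, resolves
    multi-channel co-labeling into neuron label sets, converts uncorrected
    labeling-pattern counts to exact counts by inclusion-exclusion,
    estimates per-tracer detection probabilities by capture-recapture, and
    relates co-projection rates to module overlap, injection-site distance
    and corticocortical connectivity. A synthetic-data generator with known
    ground truth makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
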