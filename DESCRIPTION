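Package: dpaan
Title: Dynamically Partitionable Autoassociative Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of dynamically partitionable autoassociative
    networks (DPAANs): Hopfield attractor networks divided into slot-like
    partitions whose between-partition synapse blocks can be gated on and
    off at run time. Provides seeded random symbol vocabularies, outer
    product (Hebbian) training, gated synchronous and asynchronous
    attractor dynamics, energy-based slot-equality detection, slot-to-slot
    semantic transfer, perceptron symbol detectors, a production-rule
    control layer, a declarative-memory module with cue-based chunk
    completion, and a match-execute runtime that reproduces the ACT-R
    Count Model. Includes demonstration runs for perceptual binding,
    syntax-sensitive rule application (the Jealousy rule), and counting,
    with raster and event-log export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
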