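Package: leafevo
Title: Phylogenetic Signal and Evolutionary Models for Leaf Physiognomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the evolution of climate-related leaf traits on
    a time-calibrated phylogeny. Derives twenty leaf physiognomy variables
    (size, shape and tooth characters) from raw leaf measurements, aggregates
    them to species, and asks whether their variation is structured by shared
    ancestry: Pagel's lambda with a likelihood-ratio test, maximum-likelihood
    fits of Brownian-motion, single-optimum Ornstein-Uhlenbeck and white-noise
    models compared by Akaike weights, phylogenetic signal representation
    (PSR) curves built from phylogenetic eigenvectors, and maximum-likelihood
    ancestral state reconstruction with traitgram coordinates. A synthetic
    data module simulates trees, trait vectors under each evolutionary model
    and geometrically valid leaf measurement tables so the whole pipeline is
    testable without herbarium data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
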