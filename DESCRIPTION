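Package: paleoniche
Title: Paleophylogeographic Species Distribution Models from Climate
    Envelopes, Phylogenies and Fossils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hindcasts species geographic ranges through
    glacial-interglacial climate cycles using rectilinear (BIOCLIM)
    climate-niche envelopes corrected for phylogenetic niche evolution
    under Brownian motion.  Provides temporally continuous paleoclimate
    interpolation between glacial and interglacial end-member grids
    driven by an isotope-proxy temperature curve, watershed-based
    dispersal masking, multivariate environmental similarity (MESS)
    scores for non-analogue climate and fossil evaluation, minimal
    refugium (SIM5) selection, partitioning of range responses into
    climate-tracking and adaptive components, and a synthetic-data
    generator that emulates all required inputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    quadprog,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
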