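Package: gillflux
Title: Pharmaceutical Transport Across Cultured Fish Gill Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bidirectional pharmaceutical transport assays on
    primary fish gill epithelia cultured on permeable inserts. Provides
    Henderson-Hasselbalch speciation and pH-corrected partitioning for
    ionizable drugs, apparent permeability (Papp) estimators with
    transepithelial-resistance gating, transport-ratio classification of
    carrier-mediated uptake and efflux, concentration-equilibrium assay
    readouts, inhibitor percent-of-control summaries, concentration-response
    regression, and a fish plasma read-across comparison. Includes a seeded
    two-compartment kinetic simulator of the cultured epithelium (passive
    transcellular flux of the neutral species, TER-dependent paracellular
    leak, saturable carrier-mediated transport, inhibitor action, counting
    and pipetting noise) that generates complete synthetic assay datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
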