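Package: trxlogo
Title: Sequence Logos with Information Content of DNA Backbone Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extends the classic sequence-logo framework to the DNA backbone.
    Shannon information content is computed both at nucleobases (4-letter
    alphabet) and at phosphate linkages, where each dinucleotide step is
    mapped to one of nine distinct values of the TRX (twist, roll,
    X-displacement) flexibility scale describing BI-BII backbone dynamics.
    Renders extended logo plots with flexibility-shaded bars at linkage
    positions, and provides the downstream statistics: flank-region
    information-content comparisons with Bonferroni correction, start-codon
    aligned codon-phase periodicity scans, bootstrap one-way ANOVA, and
    synthetic sequence-set generators for motif and coding-region data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
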