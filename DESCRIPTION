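Package: endbias
Title: Quantification and Correction of 5'/3'-End Bias in Small RNA
    Sequencing of Equimolar Reference Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling positional nucleotide biases at the 5' and
    3' ends of small RNA sequencing libraries built from equimolar reference
    pools (such as the 962-member miRXplore miRNA set), modelling per-species
    measurement error (delta log10 CPM) from terminal trinucleotide features
    with a random forest regressor, correcting abundances by subtracting the
    predicted error on the log scale, and evaluating recovery with RMSE,
    ECDF, and saturation-curve statistics.  Includes a seeded multinomial
    simulator of end-biased libraries, a compensating design rule for
    template-switching 3'-overhang primer ratios, an adapter-dimer ligation
    screen, and base-pair-maximisation proxies for self-fold and
    adapter/cDNA co-fold structure factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite,
    Biostrings,
    Rsamtools,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
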