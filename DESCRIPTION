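Package: photolag
Title: Integrated Transcriptome-Proteome Analysis of Light-Pulse Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired mRNA and protein time courses after a
    brief light pulse in fungi. Provides a pulse-driven transcription-translation
    kinetic simulator with negative-binomial count noise, isobaric-label style
    protein intensities, per-run batch effects and abundance-dependent
    whole-run missingness; transcript differential-expression calling against a
    dark control (per-condition log2 fold-changes, Welch tests, a
    P-and-twofold regulation rule, early/late timing, PCA); a proteome
    processing chain (glog variance stabilisation, batch-offset removal,
    replicate-presence filtering, k-nearest-neighbour imputation, moderated
    testing with Benjamini-Hochberg FDR); transcript-protein integration
    (pair matching, regulatory-category partition, lag correlation grids and
    mRNA-to-protein delay estimation); tight profile clustering with shape
    classification; and reporting utilities that reproduce the field's
    standard summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    deSolve,
    optparse
Config/testthat/edition: 3
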