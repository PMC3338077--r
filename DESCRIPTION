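Package: mircnv
Title: Integrated miRNA Expression and DNA Copy Number Analysis for Tumor Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for microRNA microarray expression and
    array-CGH copy number data from serially passaged tumor xenografts. Provides
    detection-call filtering and quantile normalization of Agilent-style miRNA
    feature tables, empirical-Bayes moderated t-tests with Bonferroni correction,
    presence/absence set logic across sample groups, parsing and containment
    queries for signed cytoband-interval copy-number calls, per-miRNA
    gain/loss/neutral co-localization counting against copy-number call sets,
    2^-delta-delta-Ct relative quantification for qPCR validation, and a
    seeded synthetic-data generator with planted ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
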