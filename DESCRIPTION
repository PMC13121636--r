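Package: glorid
Title: Quantitative m6A Epitranscriptome Comparison from Deamination Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of N6-methyladenosine (m6A)
    epitranscriptomes measured by chemical-deamination sequencing (GLORI-style
    assays). Starting from per-site A/G conversion-count tables, the package
    calls methylated adenosines under coverage and non-conversion thresholds,
    classifies site pentamers against the DRACH consensus, tests two-group
    differential methylation with a per-site beta-binomial likelihood-ratio
    test, aggregates site methylation per transcript and computes the
    TPM-weighted global methylation statistic that captures dilution of m6A by
    shifts in transcript abundance, builds metagene and stop-codon-centered
    differential-methylation profiles, and associates methylation status with
    alternative-polyadenylation (PDUI) changes. A seeded synthetic-data
    generator with planted ground truth supports recovery and calibration
    testing without access to sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    cluster,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
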