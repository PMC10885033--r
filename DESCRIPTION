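Package: methylscreen
Title: Expression-Ratio Specificity Screening and Threshold-Based
    Differential Methylation Calling
Version: 0.1.0
Authors@R:
    person("Maintainer", "Methylscreen", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying genes preferentially
    expressed in two dissimilar cell populations (a cell culture such as
    myoblasts, and a tissue such as cerebellum) by ratio-based screening
    of TPM/FPKM expression matrices, and for characterizing their
    differential DNA methylation from per-CpG methylomes: a
    threshold-based differentially-methylated-region (DMR) caller
    comparing replicated target methylomes against a reference panel, a
    low-methylated-region (LMR) caller against a genome-wide baseline,
    and a TSS-relative integrator producing per-gene epigenetic
    summaries.  Ships a synthetic-data generator that plants ground-truth
    gene classes and methylation regions so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
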