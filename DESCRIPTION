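Package: bequant
Title: Quantification and Prediction of CRISPR Base-Editing Outcomes at
    Endogenous Target Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies base-editing outcomes (editing efficiency, purity,
    bystander edits and 1-bp indels) from CRISPResso2-style allele-frequency
    tables, annotates target sites with endogenous transcriptional and
    epigenetic factors (peaks, expression, DNA methylation), fits sequence
    motif and convolutional per-position efficiency models, and computes full
    editing-outcome proportion distributions with a chain Bayesian network
    built from per-position Bernoulli marginals and adjacent-position odds
    ratios. Includes a synthetic-data generator with known ground truth so the
    complete pipeline can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
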