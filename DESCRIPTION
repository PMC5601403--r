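Package: apashift
Title: Alternative Polyadenylation Shift Analysis from 3' UTR Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) from bulk RNA-seq
    3' UTR coverage using a two-site change-point model of per-base read
    depth, yielding the Percentage Distal poly(A) site Usage Index (PDUI)
    per gene and sample. Provides differential APA testing between two
    phenotype groups (Fisher exact test with Benjamini-Hochberg
    adjustment), transcript integrity (TIN) quality filters, validation of
    predicted proximal sites against poly(A)-tailed read evidence,
    cohort-level PDUI shift and variability statistics, gene-set overlap
    and length-bias-aware enrichment, PDUI-input gene-set enrichment
    analysis, promoter motif scanning, and a synthetic cohort generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
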