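Package: archmpra
Title: Analysis of Massively Parallel Reporter Assays for Archaic Introgressed Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing massively parallel reporter
    assay (MPRA) experiments that test the regulatory activity of archaic
    (Neanderthal and Denisovan) introgressed variants against their modern
    human counterparts. Covers oligo library design with haplotype
    combinatorics and restriction-site screening, simulation of barcode-level
    cDNA/pDNA counts with known ground truth, count normalisation and
    filtering, per-replicate activity calling with a replicate-consensus rule,
    a precision-weighted allelic linear model with empirical-Bayes variance
    moderation, per-locus ANOVA for haplotype-like sequences, position weight
    matrix scanning with exact score p-values and differential binding scores,
    and downstream allele-frequency, TSS-distance, GC-content, concordance and
    additivity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
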