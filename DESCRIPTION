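Package: cnamet
Title: Copy-Number Aberration Analysis of Longitudinal Metastatic Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers somatic copy-number aberrations (CNAs) from matched
    tumor/normal exome coverage, scores recurrently aberrant regions with a
    GISTIC-style G-score and permutation Q-bound, compares CNA frequencies
    between treatment and response groups (test of equal proportions,
    McNemar, genome-wide Fisher scans with FDR control), scans regions for
    progression-free-survival association by permutation log-rank, and
    validates aberrations against transcript dosage with a negative-binomial
    concordance rule. Includes lesion-level objective-response
    classification from longitudinal diameters and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
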