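Package: cnapeel
Title: Driver Copy-Number Aberration Detection by G-Score Peel-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate driver copy-number aberrations in tumor
    cohorts from segmented log2-ratio profiles. Computes per-marker G-scores
    (amplitude-sum statistics, GISTIC-style) for amplifications and deletions
    under standard and sample-specific focal thresholds, assesses significance
    against a genome-wide permutation null (semi-exact histogram convolution or
    Monte-Carlo) with Benjamini-Hochberg FDR control, and iteratively reports
    peak driver regions under four peel-off variants: standard, focal,
    arm-level, and limited peel-off, which decomposes each marker's score into
    a peak-attributable and a peak-independent component so that sub-peaks
    inside broad aberrations are retained. Includes SEG and marker-matrix
    readers, IGV/BED track export, peak-to-gene annotation with a peak-shift
    permutation enrichment test, and a seeded synthetic-cohort generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
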