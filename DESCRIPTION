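Package: placemeth
Title: Placental Methylome PMD/HMD Segmentation and Differential Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for low-coverage whole-genome bisulfite
    sequencing of placental samples: reading per-CpG count tracks, tiling the
    genome into fixed windows, segmenting partially methylated domains (PMDs)
    and highly methylated domains (HMDs) with a supervised two-state Gaussian
    hidden Markov model decoded by Viterbi, estimating maternal-blood
    contamination from X-chromosome CpG-island methylation, and testing
    domain- and feature-level differential methylation between diagnostic
    groups with Welch t-tests and Benjamini-Hochberg FDR control. Includes a
    synthetic cohort generator with recorded ground truth so every stage is
    testable without protected human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
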