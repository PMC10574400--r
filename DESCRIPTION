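Package: circomp
Title: Weighted Cosine Rhythm Detection and Comparative Circadian
    Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circadian rhythmic genes in bulk RNA-seq time courses by
    weighted non-linear cosine regression with FFT-based period
    initialization, and compares circadian characteristics between two
    species. Provides a synthetic time-course count simulator with known
    oscillation ground truth, count preprocessing (expression filtering,
    trimmed-mean library scaling factors, log2 counts-per-million,
    precision/quality weights), per-gene estimation of amplitude, period,
    phase24 and baseline with standard errors and an oscillation-correlation
    rhythmicity index, classification and cross-species comparison of
    parameter distributions, homolog parameter contrasts with Holm-Sidak
    adjustment and radial-plot coordinates, and correlation-ranked gene-set
    enrichment with a cross-species normalized-enrichment-score quadrant
    comparison.
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
    edgeR,
    limma,
    fgsea,
    jsonlite
Config/testthat/edition: 3
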