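Package: rstab
Title: RNA Stability Scores and Genetic Mapping of Trans-Acting Stability Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-sample RNA stability scores (the difference in
    mean expression rank between long-lived and short-lived transcripts),
    maps genetic variants associated with the score genome-wide with
    covariate adjustment, genotype-PCA structure correction, genomic
    inflation diagnostics and permutation-based significance, performs
    Spearman cis/trans eQTL scans with Benjamini-Hochberg FDR control, and
    quantifies knockdown effects on the score. Includes a synthetic-data
    generator emulating multi-population genotype structure and
    stability-driven expression variation so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
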