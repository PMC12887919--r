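Package: dentproteo
Title: Differential Expression and Morphometrics for the Mouse Dental Proteome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-batch label-free quantitative
    proteomics of mouse molars from controlled feeding experiments.
    Implements identification-quality filtering (q-value, peptide and PSM
    thresholds), batch intersection into a combined protein group, pairwise
    treatment/control abundance ratios with censored log2 transforms,
    per-comparison significance with Benjamini-Hochberg adjustment,
    selection of consistently significant proteins across batches,
    censored fold-change summarization, hypergeometric pathway
    over-representation analysis with entity-ratio ranking against an
    inferred organism-wide background, and landmark-based phenotyping
    (inter-landmark skull length, convex-hull molar crown area, one-sided
    Welch tests). A synthetic-data generator with known ground truth
    emulates the two-batch study design, including abundance-dependent
    (missing-not-at-random) dropout, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
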