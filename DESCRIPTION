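Package: rateseqr
Title: Kinetic Analysis of 4tU Metabolic Labeling (RATE-Seq) Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-transcript mRNA synthesis rates, decay rate
    constants and half-lives from pulse-only 4-thiouracil metabolic
    labeling ("approach to equilibrium") sequencing experiments with
    whole-cell spike-in normalization. Includes a synthetic-data
    generator with known kinetic ground truth, spike-in size-factor
    normalization and low-count filtering for count matrices, nonlinear
    least-squares fitting of the labeling kinetic model with growth-rate
    correction, genotype comparison and transcript-buffering analysis
    (fold changes, rank tests, gene-set overlaps), and quantification of
    transcription-shutoff reporter decay assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
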