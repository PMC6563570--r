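Package: readerstudy
Title: Analysis and Simulation of Multi-Reader Crossover Diagnostic Accuracy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of multi-reader, multi-case (MRMC) crossover
    diagnostic accuracy studies in which every reader labels every case once
    under each of two conditions (for example, image interpretation with and
    without an AI segmentation overlay). Implements pooled (microaveraged)
    sensitivity, specificity and accuracy with Wilson score confidence
    intervals, paired one-tailed t tests on cross-reader differences with a
    radiologist-only sensitivity analysis, time-to-diagnosis summaries from
    consecutive entry times with symmetric trimming and t confidence
    intervals, exact (Conger) Fleiss kappa for interrater agreement, a
    case-level permutation test for the kappa difference between conditions,
    and Benjamini-Hochberg multiplicity control over the registered hypothesis
    family. A calibrated probit latent-trait simulator generates synthetic
    cohorts (truth tables, correlated reader annotations, reading times and
    toy voxel-probability volumes) with the study's design structure, so the
    whole pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
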