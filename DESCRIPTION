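Package: phenomod
Title: Multimodal Phenotyping and Co-Expression Contribution Analysis for
    Factorial Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for two-factor (APOE4 x humanized-Abeta)
    mouse studies of preclinical Alzheimer's disease: behavioral motif usage,
    community transition matrices and an animal-block permutation test; EEG/EMG
    sleep staging, REM architecture, NREM spindle and epileptiform spike
    detection; fEPSP slope, input-output and theta-burst LTP metrics; and a
    pseudobulk co-expression module pipeline with a module-eigengene
    contribution decomposition that apportions transcriptional change among the
    two genetic factors and their interaction. Includes seeded synthetic-data
    generators for all four modalities so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
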