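Package: siscreen
Title: Computational Histologic Screening and Stromal Inflammation Scoring
    for Tumor Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable implementation of a
    computationally-guided histologic biomarker workflow for lung squamous
    cell carcinoma tissue microarrays (TMAs). The package simulates paired
    H&E-like TMA core images with known ground truth, partitions them into
    superpixels classified as epithelium or stroma, segments nuclei and
    inflammatory cells, extracts a fixed catalogue of 1,536 morphometric and
    texture features per image (768 epithelial, 768 stromal), screens features
    against censored overall survival with a SAM-style Cox score statistic and
    permutation-based false discovery rates, computes the stromal inflammation
    (SI) score with its quantization and paired-core averaging rules, scores
    PD-L1 tumor proportion, and runs the downstream survival battery:
    Kaplan-Meier median splits, univariate and multivariate proportional
    hazards models, PD-L1 by SI interaction, and delta-value heterogeneity
    subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    survival,
    MASS,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
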