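Package: nsafDE
Title: Spectral-Count Differential Proteomics with NSAF Normalization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Label-free differential proteomics from MS/MS spectral counts.
    Implements normalized spectral abundance factor (NSAF) quantification,
    abundance-tiered differential-expression calling with tier-specific
    p-value and NSAF-ratio thresholds, presence partitioning into common and
    uniquely expressed proteins, gene-set over-representation testing, and
    directional pathway activation z-scores. Ships a negative-binomial
    spectral-count simulator with known ground truth for end-to-end
    validation, plus a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
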