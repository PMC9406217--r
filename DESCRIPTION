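Package: foxscreen
Title: Transcription-Factor Target Discovery Screen with Phenotype Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering candidate effector genes
    downstream of a transcription factor and validating the cellular
    phenotypes its loss produces. Implements differential-expression table
    filtering and fold-change ranking, position-weight-matrix promoter
    scanning with a range-normalized deficit cutoff and clustered-motif
    detection, weighted gene-set candidate scoring, an actionability decision
    tree that assigns inhibit/activate dispositions to candidates,
    dose-response growth and toxicity summarisation, DNA-content cell-cycle
    gating anchored on a synchronized control, and 3D-culture fluorescence
    image morphometry (colony counts, live/dead calls, nuclear size,
    fragmentation and anuclear fractions). A synthetic-data module generates
    every input with ground-truth labels so all stages are testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    EBImage,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
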