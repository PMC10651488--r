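Package: fbrmech
Title: Tissue-Scale Forces at the Implant Interface and Foreign-Body-Response Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models how allometrically scaled tissue forces shape the mechanical
    micro-environment around biomedical implants, and how that environment maps onto
    transcriptomic signatures of the foreign-body response (FBR). Provides a layered
    soft-tissue / disc-implant domain builder with a structured tetrahedral mesher, a
    small-strain linear-elastic finite-element solver with interface stress summaries
    and convergence checks, static and vibratory load construction with allometric
    force scaling and Young's modulus estimation from compression curves, a
    negative-binomial two-group differential-expression pipeline with
    Benjamini-Hochberg correction and ordered top-k gene signatures, a single-cell
    workflow (QC, log-normalization, mitochondrial regression, PCA, clustering, ROC
    marker detection, cross-species signature scoring, composition tables), and seeded
    synthetic-data generators for every input class so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
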