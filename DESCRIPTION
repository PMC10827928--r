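Package: crossproteo
Title: Cross-Disease Proteomic Concordance, Enrichment and Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing differential-proteome tables across diseases:
    dual-identifier (UniProt accession / gene symbol) harmonization and
    matching, directional-consistency scoring of multi-study evidence,
    same/opposite/inconsistent concordance classification, set-overlap
    enrichment (hypergeometric / Fisher) and GO-style over-representation
    with Benjamini-Hochberg FDR, weighted co-expression network analysis
    (soft thresholding, topological overlap, module detection, eigenproteins,
    module-trait correlation), and positive-pixel-count quantification of
    DAB-stained histology images. Ships synthetic-data generators with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    readxl,
    mclust,
    withr
Config/testthat/edition: 3
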