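Package: scladder
Title: Filter Ladder and NSAF Quantification for Spectral-Count Proteomics Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-search processing of label-free LC-MS/MS identification
    reports organised by a multi-dataset study design. Provides contaminant
    exclusion against a CRAPome-style frequency table, a six-stage
    identification/quantification filter ladder (two-peptide rule, confident
    score threshold, replicate- and sample-level reproducibility, CV/FC
    reliability on normalized spectral abundance factors), quartile-based
    LOW/MEDIUM/HIGH abundance categorisation, cross-dataset exclusive
    intersections, protein-list variability matrices with hierarchical
    clustering and tanglegram entanglement, and an exact Wilcoxon rank-sum
    comparison of preparation protocols. A seeded synthetic report generator
    with known ground truth supports end-to-end testing without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
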