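Package: psfsom
Title: Pathway Signal Flow Portraits and Spot-Based Disease Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Topology-based pathway activity analysis for case/control
    transcriptome cohorts. Propagates gene-level fold changes through
    signed (activation/inhibition) pathway graphs to obtain per-branch
    pathway signal flow (PSF) activities, summarizes sink-wise activity
    profiles on a self-organizing map as sample and disease portraits,
    detects co-regulated spots on the summary map, builds a spot-sharing
    disease similarity graph with walktrap community detection, and
    annotates spots by hypergeometric overrepresentation analysis.
    Includes a synthetic multi-cohort generator with planted pathway
    perturbations for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
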