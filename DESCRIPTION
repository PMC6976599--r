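Package: moanet
Title: Multi-Omics Mode-of-Action Inference with Prize-Collecting Steiner
    Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates differential multi-omics evidence (transcripts,
    proteins, phosphosites, untargeted metabolite peaks, predicted
    transcription factors) on a heterogeneous molecular interactome and
    extracts compact candidate mode-of-action subnetworks with a
    Prize-Collecting Steiner Forest optimization. Includes adduct-aware
    ppm matching of untargeted m/z peaks to metabolites, randomization
    based robustness and specificity filtering of solution nodes,
    hypergeometric pathway enrichment, motif-based transcription-factor
    prediction, and a synthetic-data generator with planted ground truth
    for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
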