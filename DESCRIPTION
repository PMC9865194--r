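Package: epiorigin
Title: Tissue- and Cell-of-Origin Prediction from Regional Mutation
    Density and Chromatin Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks tissue- and cell-type chromatin-mark features (ChIP-seq
    read counts per fixed-width genomic window) by how well they explain the
    regional somatic mutation density landscape of a sample, using a
    gradient-boosted tree regressor with importance-based screening and
    greedy backward elimination; the tissue or cell type of the last
    surviving feature is reported as the putative tissue- or cell-of-origin.
    Includes a random-forest baseline ranker driven by out-of-bag
    permutation importance, region-subset and enhancer-proportion
    robustness analyses, genome-window construction with exclusion
    filtering, per-sample mutation profiling, and a synthetic-data
    generator with a planted origin signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
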