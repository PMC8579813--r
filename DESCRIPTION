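Package: regufoot
Title: Regulon Reconstruction by Phylogenetic Footprinting of Bacterial
    Upstream Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics reconstruction of bacterial
    transcription-factor regulons: symmetry-constrained de novo binding-site
    motif discovery by expectation-maximization (palindromes, tandem repeats,
    and spaced inverted repeats) over orthologous upstream regions, positional
    weight matrix scanning with a minimum-training-score threshold,
    cross-genome consistency filtering of candidate sites, transcription start
    site and sigma-A promoter anchored repressor/activator classification, and
    a differential-expression overlay that cross-tabulates regulon membership
    with substrate-specific induction.  Includes a ground-truthed synthetic
    data generator emulating a multi-genome study design for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
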