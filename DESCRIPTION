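Package: rddm
Title: Analysis Toolkit for RNA-Directed DNA Methylation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis chain of plant RNA-directed
    DNA methylation (RdDM) studies: tiling-window differential DNA methylation
    and DMR calling from whole-genome bisulfite data, hits-normalized abundance
    (HNA) quantification of multimapping small RNAs and siRNA-depleted-region
    calling, mutant-panel classification of siRNA clusters into Pol IV-only and
    Pol V-dependent classes, input-normalized log2 ChIP enrichment with ranked
    and metagene profiles, cross-omic integration summaries, and one-site
    binding-isotherm fitting of isothermal titration calorimetry data. A
    synthetic-data generator plants ground truth at every stage so each method
    can be benchmarked end to end.
License: MIT
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
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
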