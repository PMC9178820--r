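Package: genage
Title: Phylostratigraphic Gene Ages and Age-Stratified Regulatory Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns evolutionary ages (phylostrata) to genes from a species
    tree and protein best-hit tables using the deepest-clade rule, and provides
    age-stratified analyses of regulatory genomics data: open-chromatin peak
    filtering and TSS-proximal/distal classification, enhancer-nearest-gene
    association, metagene coverage profiles around transcription start sites,
    rule-based annotation of nonsense-mediated decay (NMD) features from gene
    models, and nonparametric group comparisons of expression, mRNA half-life,
    ribosome association and monosome scores.  A synthetic-data generator
    emits a complete toy genome with planted age-dependent structure so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    ape,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
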