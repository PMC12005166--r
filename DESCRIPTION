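Package: popbaseline
Title: Two-Step Demographic and Fitness-Effect Inference for Coding-Sparse Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds evolutionary baseline models for species with coding-sparse
    genomes in two steps: demographic inference on curated nonfunctional regions
    by coalescent simulation and grid-search fitting of an 18-statistic summary
    vector (segregating sites, Tajima's D, mean r-squared per population and
    Hudson F_ST per population pair), followed by inference of the distribution
    of fitness effects on functional regions with a native forward Wright-Fisher
    simulator conditioned on the fitted demography. Includes a synthetic-data
    generator emulating VCF/BED/GFF3/rate-map inputs with recorded ground truth,
    selective-sweep simulation (recurrent and conditioned single sweeps), and
    sweep-detectability evaluation with a composite likelihood ratio scan and
    windowed H12, summarised as ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
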