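Package: oralsite
Title: Saliva and Buccal-Mucosa Microbiome Comparison, Assembly Inference,
    and Personal Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of paired saliva and buccal-mucosa
    16S rRNA communities starting from an ASV feature table: table preparation
    (singleton removal, rarefaction to 95% of the minimum depth, rank
    collapse), alpha and beta diversity with group statistics, Sloan
    neutral-community-model fitting and null-model deterministic-strength
    estimation, random-forest habitat-of-origin classification with top-k
    importance refitting, and personal discrimination via rank-threshold
    unique species and a renormalized core-genus "microbial code". A seeded
    synthetic paired-habitat community generator reproduces the statistical
    structure every stage assumes, so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
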