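Package: bafdep
Title: Quantifying and Predicting BAF-Dependent Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chromatin accessibility changes under acute
    inhibition of BAF (mammalian SWI/SNF) chromatin remodeling complexes.
    Provides interval arithmetic and readers for BED/narrowPeak peak files,
    annotation of accessible regions into cis-regulatory element classes
    (promoters, active/primed/poised enhancers, CTCF-bound elements),
    invariant-gene size-factor normalization with negative-binomial
    differential testing suited to global signal loss, a random-forest and
    ridge-regression framework ranking chromatin features that predict
    accessibility loss, the tau tissue-specificity index, promoter-capture
    Hi-C gene-enhancer link enrichment, and a seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
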