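Package: aimut
Title: Allelic Imbalance of Somatic Mutations Between Genome and Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allelic imbalance (AI) between DNA-level and RNA-level
    mutant allele fractions of somatic mutations using a two-sample
    beta-binomial Bayes-factor test, annotates truncating mutations for
    nonsense-mediated decay (NMD) sensitivity from transcript geometry
    (the 50-nt rule and related positional features), classifies canonical
    splice-site mutations, and provides the downstream enrichment
    statistics (Fisher and chi-square tests, mutation spectra,
    transition/transversion summaries, cumulative ratio curves, per-gene
    AI enrichment with ranked-list export). A synthetic-cohort generator
    with known ground truth replaces controlled-access tumor sequencing
    data so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
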