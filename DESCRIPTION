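Package: pirnakit
Title: Small RNA Analysis and Simulation Tools for piRNA Cluster Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for studying environmentally induced
    activation of piRNA clusters from tandem transgene arrays. Provides a
    seeded synthetic small-RNA data generator (toy genomes, adapter-terminated
    FASTQ libraries with controlled ping-pong structure, qPCR plates,
    conversion count tables), an exact 0/1-mismatch short-read mapper,
    normalized size and coverage profiles, ping-pong overlap signature
    z-scores with 1U/10A composition statistics, a 50-kb genome window scan
    for de novo piRNA producing loci, repression-frequency and homogeneity
    chi-square statistics, absolute and strand-specific qPCR quantification
    arithmetic, and a stochastic transgenerational epiallele conversion
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
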