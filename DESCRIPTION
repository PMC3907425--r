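Package: methylfiltr
Title: Gene-Space Analysis of Methylation-Filtered Shotgun Libraries
Version: 0.1.0
Authors@R:
    person("MPOB", "Bioinformatics", email = "devnull@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome survey sequencing performed with
    methylation filtration, in which a bacterial cloning strain degrades
    methylated (repeat-rich) DNA so that sequenced clones over-represent the
    hypomethylated, gene-rich fraction of a plant genome. Implements the two
    classical estimators of filter power and effective sampled genome size
    (the direct gene-hit probability ratio, and a piecewise Lander-Waterman
    island-count inversion for mixed filtered/unfiltered assemblies),
    single-linkage island clustering with assembly summary statistics,
    microsatellite mining with imperfection budgets and canonical motif
    classes, pileup-based SNP calling with transition/transversion spectra
    and density estimates, iterative subtractive hybridisation for gene-space
    coverage, and rule-based classifiers for gene-model QC, plant resistance
    gene classes and miRNA precursor matches. A synthetic-data module
    simulates genomes with annotated gene/repeat/methylated intervals,
    filtered and unfiltered read libraries, and variant-bearing multi-read
    pileups so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
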