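Package: splicehex
Title: Splice-Site Usage, Single-Site Association Mapping and Hexamer Rankings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the usage of individual splice donor and acceptor
    sites from splice-junction read counts (the splice-site strength
    estimate, SSE), computes variability and broad-sense heritability of
    usage across replicated genotype panels, maps per-site genetic
    associations with Manhattan-plot peak calling and cis/trans
    classification, analyses position-wise and pairwise nucleotide effects
    on usage, ranks intron-terminal GT[N]4 / [N]4AG hexamers by their
    average usage, scores how many splice-site choices those rankings
    explain, and evaluates competing donor pairs in minigene libraries
    against a permutation null. Ships a synthetic-data generator with
    hexamer-determined ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
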