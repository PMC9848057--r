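Package: arrayscan
Title: Tandem Gene-Array Homogenization and Tissue-Specificity Analysis
Version: 1.0.0
Authors@R:
    person("Array", "Scan Developers", email = "arrayscan@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of tandem gene-family homogenization and
    tissue-specific expression in mammalian genomes, motivated by the study of
    keratin-associated protein (KRTAP) arrays and the epidermal differentiation
    complex. Provides Human-Protein-Atlas-style TPM tissue-specificity
    classification with a fold-change/FDR differential screen, amino-acid and
    GC composition statistics with a tyrosine candidate screen, pairwise
    protein alignment and p-distance profiles over tandem arrays, a
    Nei-Gojobori (1986) synonymous-substitution estimator with Jukes-Cantor
    correction and molecular-clock dating, conserved-noncoding-element decay
    scoring from alignment coverage, and a forward-time simulator of tandem
    arrays evolving under duplication, point mutation and nonallelic gene
    conversion so that every stage is verifiable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
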