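Package: phevokit
Title: Analysis of Phage Community Experimental Evolution on Capsule-Diverse Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of experimental evolution of a
    bacteriophage community on a capsule-diverse Klebsiella host panel.
    Tracks community composition from mapped-read shares with diagnostic-site
    deconvolution of closely related phage pairs, scores spot tests and
    efficiency of plating (EOP) with detection-limit handling, classifies
    variants against CDS annotations and tests receptor-binding-protein (RBP)
    mutation enrichment with an exact comparison of Poisson rates, computes a
    Nei-Gojobori counting dN/dS screen, paints recombinant genomes against two
    parents from informative sites to call breakpoints and RBP swaps, and
    compares variant-calling versus whole-genome-alignment detection with
    Fisher's exact test. A synthetic-community generator emulates the full
    experiment (genomes, annotations, passage dynamics, variant calls,
    recombinants, plating assays) with known ground truth so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
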