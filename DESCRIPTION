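Package: tetrimito
Title: Comparative Mitogenomics of Pygmy Grasshopper Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of insect mitochondrial genomes,
    built around the Tetrigidae (pygmy grasshopper) study system: a circular
    annotated-mitogenome data model with GenBank flat-file and FASTA I/O;
    nucleotide composition, AT/GC skews and sliding-window content profiles;
    codon-usage-bias statistics under the invertebrate mitochondrial code
    (RSCU, effective number of codons, positional GC and the GC12-on-GC3
    neutrality regression, with clustered RSCU matrices); intergenic-gap
    scanning with cloverleaf tRNA candidate prediction; phylogenomic
    supermatrix construction with partition output and a light
    distance/neighbour-joining stage; and a synthetic mitogenome generator
    with known truth so every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    phangorn,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
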