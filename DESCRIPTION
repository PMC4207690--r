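Package: semtype
Title: Seminal Microbiome Community Typing and Semen-Quality Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for profiling seminal bacterial communities
    from paired-end 16S rRNA (V4) amplicon reads and relating them to semen
    quality. Covers barcode demultiplexing and Phred-based quality filtering,
    97 percent-identity paired-end taxonomic assignment, proportion-based
    genus and species profiles, weighted UniFrac beta diversity, community
    typing by UPGMA clustering with the Calinski-Harabasz pseudo-F, Shannon
    and Chao1 alpha diversity, Spearman co-occurrence networks, case versus
    normal differential abundance with adaptive Benjamini-Hochberg FDR
    control, Fisher enrichment statistics, and a C4.5-style decision-rule
    classifier of community type over genus-ratio features. Includes a fully
    self-contained synthetic cohort generator (reference sequences, rooted
    phylogeny, paired FASTQ reads and clinical metadata) that emulates the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    phangorn,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
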