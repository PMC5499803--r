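Package: rflscout
Title: Identification of PPR Genes, RFL Candidates and RFL Generation
    Hotspots in Plant Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for candidate restorer-of-fertility (Rf)
    genes in plant genomes. Pentatricopeptide repeat (PPR) proteins are
    located in a proteome by position-specific scoring-matrix scans (or
    imported HMMER hits), classified into the P and PLS subfamilies and the
    E, E+ and DYW subclasses, and restorer-of-fertility-like (RFL)
    candidates are called by combining greedy identity clustering with
    homology to known restorer proteins. A simplified orthologous-clustering
    stage (reciprocal-best-hit pair calling plus Markov clustering) locates
    the characteristic RFL supercluster across species, and a
    neighbor-joining phylogeny of that cluster yields species-specific
    clades that map to compact genomic regions of active RFL generation
    ("hotspots"). A seeded multi-species simulator with full ground truth
    supports closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
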