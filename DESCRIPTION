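Package: magcat
Title: Quality Gating, Dereplication and Annotation Analytics for
    Metagenome-Assembled Genome Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing catalogs of
    metagenome-assembled genomes (MAGs). Implements MIMAG-style quality
    scoring and tiering, MinHash sketch prefiltering and anchor-chain
    average nucleotide identity (ANI) with per-genome aligned fractions,
    greedy centroid clustering into species-level operational taxonomic
    units (OTUs) with novelty calling against reference genomes, relative
    evolutionary divergence (RED) rank delineation with adjusted mutual
    information calibration, phylogenetic diversity gain, rule-based
    virus-host linkage via CRISPR spacers, sequence matches and prophage
    predictions, biosynthetic gene cluster screening, and post-alignment
    read-recruitment summaries. Seeded synthetic-data generators provide
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Rcpp,
    ape,
    phytools,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
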