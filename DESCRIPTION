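Package: homolograph
Title: Annotation-Free Delineation of Maximal Homologous Groups in
    Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions a set of bacterial genome assemblies into maximal
    homologous groups (MHGs) of sequences without relying on gene
    annotations.  Pairwise local alignments (BLAST tabular input or a
    built-in exact aligner for small fixtures) are piled up into an
    alignment graph whose edges are traversed to propagate breakpoints
    through per-alignment bit arrays, partitioning and merging homology
    groups until every group is homologous across its full length.  Also
    provides occurrence and coverage analytics over the resulting
    partition, a recombinant-marker simulation study (chained
    nearest-neighbor-interchange component trees, Jukes-Cantor sequence
    simulation, neighbor-joining inference with bootstrap), bipartition
    normalization and Robinson-Foulds conflict analytics, and a synthetic
    genome generator with planted ground-truth homology for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    phangorn,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
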