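Package: retroscape
Title: Segmental Duplications, Gene Retrocopies and Retrotransposition
    Hallmarks in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene duplication in genome assemblies, with
    canine genomes as the motivating system. Detects pairwise segmental
    duplications by genome self-alignment, merges them into duplicated
    intervals, locates short high-recurrence segments, and tests for
    enrichment near chromosome ends by permutation. Converts sequencing
    depth tracks into GC-corrected per-window copy-number estimates and
    calls duplicated regions and duplicated genes. Builds representative
    cDNAs, discovers retrocopies (processed gene copies) by an alignment
    filter cascade, and annotates retrotransposition hallmarks:
    target-site duplications by local alignment of insertion flanks,
    poly(A) tails by homopolymer-run rules, and LINE-1 endonuclease
    cleavage-site motifs. Compares retrocopy presence across assemblies
    by flank mapping and estimates the per-generation retrocopy insertion
    rate calibrated by a single-nucleotide mutation rate. A synthetic
    genome generator plants duplications, multi-exon genes, retrocopies
    and diverged sister assemblies with full ground truth so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
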