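Package: rilmap
Title: Sequence-Defined Genetic Linkage Maps from RAD-Seq of Recombinant
    Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building sequence-defined genetic linkage maps from
    restriction-site associated DNA sequencing (RAD-seq) of biparental
    recombinant inbred line (RIL) populations. Includes a meiosis-level
    simulator of founder genomes, single-seed-descent pedigrees and barcoded
    EcoRI RAD libraries; k-mer depth-histogram profiling for genome-size and
    coverage estimation; demultiplexing, tag clustering and SNP/indel marker
    genotyping; two-point linkage analysis with the Haldane-Waddington
    correction for selfing RILs, LOD-threshold grouping and
    recombination-count (RECORD-style) marker ordering; anchoring of assembly
    scaffolds onto the map by unique exact tag match; and co-segregation
    scanning for markers linked to binary monogenic traits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    S4Vectors,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
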