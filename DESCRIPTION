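Package: igjunction
Title: Immunoglobulin V(D)J Junction Annotation and Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of expressed immunoglobulin repertoires from 5'-RACE
    amplicon reads: germline V/D/J gene loading, IMGT-style functionality
    classification and clan clustering, fuzzy recombination-signal-sequence
    (RSS) scanning, primer/length read screening, template V(D)J assignment by
    pairwise alignment, CDR3 anchoring between the conserved Cys and Trp/Phe
    motifs, decomposition of junctions into germline-retained, palindromic (P)
    and non-templated (N) nucleotides with exonucleolytic trimming counts,
    somatic hypermutation frequency, per-site profiles, substitution spectra
    and AID-hotspot (WRCY/RGYW) analysis, and segment-usage statistics.
    Includes a seeded V(D)J recombination read simulator with full per-read
    ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
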