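Package: psifinder
Title: Pseudouridine Detection in Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects pseudouridine (Psi) in small RNAs from three
    complementary sequencing readouts: antibody immunoprecipitation
    (IP/unbound enrichment), CMC-mediated library depletion under standard
    reverse transcription (CMC+/mock depletion), and CMC/Mn2+ mutational
    readout (deletion and mismatch signatures at Psi positions). Provides a
    molecule-level synthetic read generator that emulates the underlying
    chemistry with known per-site stoichiometry, a small RNA preprocessing
    stack (adapter trimming, length/quality filtering, read collapsing), a
    desk-scale verifiable aligner with a single-deletion mode, paired
    negative-binomial Wald enrichment testing with median-of-ratios
    normalization, nucleotide-resolution site calling, transposon-family and
    tRNA-fragment rollups, metagene coverage profiles, and a deterministic
    end-to-end pipeline with parameter-recovery reporting.
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
    Rcpp,
    jsonlite,
    yaml,
    zoo,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
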