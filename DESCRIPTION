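Package: captrans
Title: Translatome Analysis of Transcription Start Sites from CapSeq
    Polysome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies capped 5'-end (CapSeq) reads per transcription
    start site and promoter across polysome-fraction pools, computes
    ribosome occupancy and its response to energy stress, calls
    translationally affected promoters and differentially translated
    alternative-promoter pairs, classifies TOP (CYYYY) promoters and
    initiating-nucleotide contexts, builds metagene TSS profiles, and
    fits eIF4E-cap dissociation constants from fluorescence titrations.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
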