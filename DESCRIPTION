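Package: riboprof
Title: Tissue-Specific Ribosome Profiling Analysis and Read Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies transcriptional (RNA-seq), translational (TRAP), and
    ribosome-footprint sequencing data on transcript coordinates; computes and
    classifies translation efficiency; calls differential transcription and
    translation with a weighted beta-binomial t-type test and a two-criteria
    translational-regulation rule; detects global translational shifts with a
    Kolmogorov-Smirnov fold-change analysis; and validates every stage against
    a built-in simulator of RNase-T1-digested ribosome footprints and full
    length mRNA reads with negative-binomial replicate noise and genotype
    perturbations (locus deletions, UTR-swapped transgenes, global translation
    efficiency shifts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
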