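Package: phagechar
Title: In Silico Characterization of 936-Type Lactococcal Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational characterization toolkit for cos-ended dairy
    bacteriophage genomes, centred on the 936-type phages of Lactococcus
    lactis. Provides in-silico restriction fragment length polymorphism
    (RFLP) typing with cohesive-end (cos) handling, in-silico multiplex PCR
    typing, ORF calling and transcription-region partitioning, cos-region
    repeat and terminase-site mapping, +1 ribosomal frameshift (shifty-stop)
    simulation of major tail protein fusions, one-step growth curve
    parameter estimation, alignment-free k-mer distances with
    neighbour-joining trees, dot-plot synteny segment extraction, and a
    synthetic genome generator that plants all of these features with
    recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
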