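Package: memotif
Title: Memetic De Novo DNA Motif Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: De novo discovery of transcription factor binding motifs in DNA
    sequence sets using a memetic optimization framework: GRASP-style
    semi-greedy construction of start-position alignments, a genetic algorithm
    with variable neighborhood search as the mutation operator, and a
    bi-objective position-specific score matrix fitness combining information
    content with a sequence-complexity penalty. Discovered models are used to
    call motif occurrences by Gaussian z-score/p-value scanning. Includes
    DUST-style low-complexity masking, a planted-motif synthetic data
    generator, and a tolerance-window precision/recall evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
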