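Package: fanzortrace
Title: Motif Fingerprinting, Transposon Curation and Guide-RNA Analysis for
    TnpB/Fanzor Nucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing eukaryotic Fanzor nucleases to their IS607
    TnpB relatives. Implements RuvC/zinc-finger motif fingerprint
    classification of TnpB-family proteins, iterative position-specific
    scoring matrix (PSSM) homology search with alignment augmentation,
    transposon locus curation (target-site duplications, terminal inverted
    repeats, IS607 GG crossover boundaries) and insertion-sequence family
    assignment from neighbour-gene domain annotations, transposon-associated
    motif (TAM) depletion scoring with sequence-logo matrices, TnpA-TnpB
    co-conservation analysis over percent-identity matrices, and right-end
    RNA (reRNA) boundary calling with pseudoknot complementarity checks.
    Every input the pipeline consumes can be simulated with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
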