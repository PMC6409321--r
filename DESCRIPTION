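Package: knotfold
Title: RNA Secondary Structure Prediction with Pseudoknots via Sequence
    Labelling and Compatible Stem Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structures, including pseudoknots, by
    combining a per-base structural labeller with a combinatorial correction
    stage.  A bidirectional LSTM encoder-decoder (or a pluggable noisy
    oracle) labels each base with one of seven extended dot-bracket symbols;
    a correction unit then assembles an optimal set of mutually compatible
    stems from the labelled complementary regions, builds up to three
    pseudoknot-free substructures, and merges them into a pseudoknotted
    structure.  Includes readers and writers for FASTA, CT, BPSEQ and
    extended dot-bracket formats, pair-level sensitivity/PPV/F-score
    evaluation, and a synthetic-instance generator with planted stems and a
    configurable label-noise model so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    igraph,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
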